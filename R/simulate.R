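## Synthetic cohort generator. Emulates the five-cluster structure of the
## reference 119-patient cohort: per-cluster truncated-normal numeric
## attributes, per-cluster categorical label frequencies, independent
## Bernoulli manifestations, and the published perinatal outcome pattern.

## evaluate expr under a given RNG seed without disturbing the caller's RNG
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

## truncated normal by rejection sampling; degenerate sd returns the mean
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (n == 0) return(numeric(0))
  if (sd <= 0) return(rep(min(max(mean, lower), upper), n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Default parameters of the synthetic cohort generator
#'
#' Returns the generator configuration that emulates the reference
#' 119-patient cohort: cluster sizes 33/27/16/19/24, per-cluster numeric
#' means/SDs, lab-label, delivery-type, dipstick-grade and manifestation
#' frequencies, perinatal outcome parameters, and the default missingness
#' pattern.
#'
#' @param size_factor Positive number scaling every cluster size (e.g. 100
#'   for parameter-recovery checks at large n).
#' @param sd_scale Positive factor applied to every numeric-attribute SD;
#'   values < 1 sharpen cluster separation for recovery experiments.
#' @param fetal_loss_source `"perinatal"` (default) places all 21 fetal
#'   losses in cluster 1 as the perinatal outcome table states;
#'   `"delivery"` instead draws delivery types (including FD) from the
#'   delivery-type count table, which spreads 22 losses as 20/1/1/0/0.
#' @return A `cohort_parameters` list.
#' @export
cohort_parameters <- function(size_factor = 1, sd_scale = 1,
                              fetal_loss_source = c("perinatal", "delivery")) {
  stopifnot(size_factor > 0, sd_scale > 0)
  fetal_loss_source <- match.arg(fetal_loss_source)
  numeric_params <- reference_numeric_params()
  for (v in names(numeric_params)) {
    numeric_params[[v]]$sd <- numeric_params[[v]]$sd * sd_scale
  }
  ## newborn weight and Apgar are numeric attributes too: their SDs follow
  ## the same scale factor
  peri <- reference_perinatal_summary()
  peri$weight_sd <- peri$weight_sd * sd_scale
  peri$apgar_sd <- peri$apgar_sd * sd_scale
  sizes <- as.integer(round(peri$size * size_factor))
  structure(list(
    cluster_sizes = sizes,
    numeric_params = numeric_params,
    numeric_bounds = list(disease_duration_y = c(0, Inf),
                          maternal_age_y = c(18, 45),
                          gestational_age_d = c(35, 300)),
    lab_counts = reference_lab_counts(),
    delivery_counts = reference_delivery_counts(),
    manifestation_counts = reference_manifestation_counts(),
    protein_counts = reference_protein_counts(),
    perinatal = peri,
    size_factor = size_factor,
    fetal_loss_source = fetal_loss_source,
    missingness = reference_missingness()
  ), class = "cohort_parameters")
}

#' Generate a synthetic cohort with planted cluster structure
#'
#' Draws a cohort from the per-cluster distributions in `params`:
#' numeric attributes from truncated normals (disease duration >= 0,
#' maternal age 18-45, gestational age 35-300 days), obstetric counts
#' (G/P/A/L) rounded to non-negative integers with para <= gravid enforced
#' by resampling, lab labels / delivery types / dipstick grades from the
#' per-cluster count proportions, manifestations as independent Bernoulli
#' draws, and perinatal outcomes (fetal loss, term/preterm, newborn weight,
#' 1-minute Apgar) from the perinatal parameters. Fetal losses receive
#' Apgar 0. Deterministic given `seed`.
#'
#' @param params A [cohort_parameters()] configuration.
#' @param seed Integer seed governing all randomness.
#' @return A list with `cohort` (an `sle_cohort`) and `labels` (integer
#'   vector of true cluster indices, the planted ground truth).
#' @export
generate_cohort <- function(params = cohort_parameters(), seed = 1) {
  stopifnot(inherits(params, "cohort_parameters"))
  sizes <- params$cluster_sizes
  if (any(sizes <= 0)) stop("cluster sizes must be positive", call. = FALSE)
  k_n <- length(sizes)
  f <- params$size_factor
  peri <- params$perinatal
  if (params$fetal_loss_source == "perinatal") {
    losses <- round(peri$fetal_losses * f)
  } else {
    losses <- round(params$delivery_counts[, "FD"] * f)
  }
  if (any(losses > sizes)) {
    stop("infeasible config: fetal-loss count exceeds cluster size",
         call. = FALSE)
  }

  with_local_seed(seed, {
    rows <- vector("list", k_n)
    for (k in seq_len(k_n)) {
      n_k <- sizes[k]
      df <- data.frame(patient_id = rep(NA_character_, n_k),
                       stringsAsFactors = FALSE)
      for (v in names(params$numeric_params)) {
        p <- params$numeric_params[[v]]
        b <- params$numeric_bounds[[v]]
        if (is.null(b)) b <- c(-Inf, Inf)
        df[[v]] <- rtrunc_norm(n_k, p$mean[k], p$sd[k], b[1], b[2])
      }
      df$disease_duration_y <- round(df$disease_duration_y, 2)
      df$maternal_age_y <- round(df$maternal_age_y, 1)
      df$gestational_age_d <- round(df$gestational_age_d)
      ## obstetric counts: integers >= 0, gravid >= 1 (all are pregnant),
      ## para <= gravid enforced by resampling the pair
      gp <- params$numeric_params
      df$gravid <- pmax(1, round(df$gravid))
      df$para <- pmax(0, round(df$para))
      bad <- which(df$para > df$gravid)
      while (length(bad)) {
        df$gravid[bad] <- pmax(1, round(rtrunc_norm(
          length(bad), gp$gravid$mean[k], gp$gravid$sd[k], 0, Inf)))
        df$para[bad] <- pmax(0, round(rtrunc_norm(
          length(bad), gp$para$mean[k], gp$para$sd[k], 0, Inf)))
        bad <- which(df$para > df$gravid)
      }
      df$abortion <- pmax(0, round(df$abortion))
      df$live <- pmax(0, round(df$live))

      pc <- params$protein_counts[, k]
      df$urinary_protein_grade <- sample(dipstick_grades(), n_k,
                                         replace = TRUE, prob = pc / sum(pc))
      lc <- params$lab_counts[[k]]
      for (v in lab_variables()) {
        df[[v]] <- sample(lab_levels(), n_k, replace = TRUE,
                          prob = lc[, v] / sum(lc[, v]))
      }
      mprob <- params$manifestation_counts[, k] / peri$size[k]
      for (j in seq_len(15)) {
        df[[paste0("y", j)]] <- as.numeric(stats::runif(n_k) < mprob[j])
      }

      loss_k <- losses[k]
      is_loss <- rep(FALSE, n_k)
      if (loss_k > 0) is_loss[sample.int(n_k, loss_k)] <- TRUE
      df$live_birth <- as.numeric(!is_loss)
      dc <- params$delivery_counts[k, ]
      df$delivery_type <- NA_character_
      df$delivery_type[is_loss] <- "FD"
      n_live <- sum(!is_loss)
      if (n_live > 0) {
        live_probs <- dc[c("CS", "ND")]
        if (sum(live_probs) == 0) live_probs <- c(CS = 1, ND = 0)
        df$delivery_type[!is_loss] <- sample(
          c("CS", "ND"), n_live, replace = TRUE,
          prob = live_probs / sum(live_probs))
      }
      p_term <- if (peri$term[k] + peri$preterm[k] > 0) {
        peri$term[k] / (peri$term[k] + peri$preterm[k])
      } else 0
      df$term <- 0
      df$term[!is_loss] <- as.numeric(stats::runif(n_live) < p_term)
      df$newborn_weight_g <- round(rtrunc_norm(
        n_k, peri$weight_mean[k], peri$weight_sd[k], 0, Inf))
      df$apgar_1min <- round(rtrunc_norm(
        n_k, peri$apgar_mean[k], peri$apgar_sd[k], 0, 10))
      df$apgar_1min[is_loss] <- 0
      rows[[k]] <- df
    }
    df <- do.call(rbind, rows)
    df$patient_id <- sprintf("P%04d", seq_len(nrow(df)))
    list(cohort = as_sle_cohort(df),
         labels = rep(seq_len(k_n), sizes))
  })
}

#' Mask values at random to emulate registry missingness
#'
#' Sets exactly `spec[v]` values of each named variable to missing, chosen
#' uniformly at random among the patients; deterministic given `seed`. The
#' default [reference_missingness()] pattern masks dsDNA/ANA in 5 patients
#' each, APL in 7, and SSA/SSB in 4 each.
#'
#' @param cohort An `sle_cohort`.
#' @param spec Named integer vector (variable -> number of masked patients).
#' @param seed Integer seed.
#' @return The cohort with the requested cells set to `NA`.
#' @export
inject_missingness <- function(cohort, spec = reference_missingness(),
                               seed = 1) {
  stopifnot(inherits(cohort, "sle_cohort"))
  if (length(spec) == 0) return(cohort)
  unknown <- setdiff(names(spec), cohort_columns())
  if (length(unknown)) {
    stop("missingness spec names unknown variable(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  n <- n_patients(cohort)
  if (any(spec > n)) {
    stop("missingness count exceeds cohort size", call. = FALSE)
  }
  with_local_seed(seed, {
    for (v in names(spec)) {
      if (spec[[v]] > 0) {
        cohort$data[[v]][sample.int(n, spec[[v]])] <- NA
      }
    }
    cohort
  })
}
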