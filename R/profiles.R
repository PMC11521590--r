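## Cluster profiling and high/moderate/low risk-tier assignment.

#' Percentage of a count with an explicit rounding mode
#'
#' Computes 100 * count / total and rounds to `digits` decimals either by
#' round-half-up (default, used for cohort shares) or by truncation (used
#' for the outcome percentages, which the source reports truncated).
#'
#' @param count,total Numerator and denominator counts.
#' @param digits Decimal places.
#' @param mode `"half_up"` or `"truncate"`.
#' @return Numeric percentage(s).
#' @export
percent_of <- function(count, total, digits = 2,
                       mode = c("half_up", "truncate")) {
  mode <- match.arg(mode)
  x <- 100 * count / total
  f <- 10^digits
  ## 1e-9 guards against values like 26.800000000000004 truncating to 26.7
  switch(mode,
         half_up = floor(x * f + 0.5 + 1e-9) / f,
         truncate = floor(x * f + 1e-9) / f)
}

#' Per-cluster share of the cohort
#'
#' @param assignment A `cluster_assignment` (or a bare vector of counts).
#' @param digits,mode Passed to [percent_of()]; defaults give two-decimal
#'   round-half-up shares.
#' @return Numeric vector of percentages, one per cluster.
#' @export
cluster_share <- function(assignment, digits = 2, mode = "half_up") {
  counts <- if (inherits(assignment, "cluster_assignment")) {
    assignment$counts
  } else {
    as.numeric(assignment)
  }
  if (!length(counts) || sum(counts) == 0) {
    stop("empty assignment", call. = FALSE)
  }
  percent_of(counts, sum(counts), digits = digits, mode = mode)
}

#' Summarise each cluster's maternal and perinatal characteristics
#'
#' For each cluster: patient count and cohort share; per-manifestation
#' counts and percentages (of the whole cohort); mean +/- SD of the numeric
#' attributes (sample SD, n - 1 denominator; single-patient clusters report
#' SD 0 with a degeneracy flag); lab-label and delivery-type count tables;
#' and the perinatal summary (live births, fetal losses, term/preterm,
#' newborn weight and 1-minute Apgar mean +/- SD).
#'
#' @param cohort An imputed `sle_cohort`.
#' @param assignment A `cluster_assignment` over the same patients.
#' @return A `cluster_profiles` object (list of per-cluster profiles).
#' @export
profile_clusters <- function(cohort, assignment) {
  stopifnot(inherits(cohort, "sle_cohort"),
            inherits(assignment, "cluster_assignment"))
  df <- cohort$data
  n <- nrow(df)
  if (n != length(assignment$cluster)) {
    stop("assignment does not partition the cohort", call. = FALSE)
  }
  numvars <- c("disease_duration_y", "maternal_age_y", "gestational_age_d",
               "gravid", "para", "abortion", "live")
  profiles <- lapply(seq_len(assignment$k), function(ci) {
    idx <- assignment$cluster == ci
    size <- sum(idx)
    if (size == 0) stop("empty cluster ", ci, call. = FALSE)
    sub <- df[idx, , drop = FALSE]
    degenerate <- size < 2
    msd <- function(x) {
      c(mean = mean(x), sd = if (degenerate) 0 else stats::sd(x))
    }
    man_counts <- vapply(manifestation_variables(),
                         function(v) sum(sub[[v]]), numeric(1))
    live_births <- sum(sub$live_birth == 1)
    lw <- sub$newborn_weight_g
    la <- sub$apgar_1min
    list(
      cluster = ci,
      size = size,
      share_pct = percent_of(size, n),
      degenerate = degenerate,
      manifestation_counts = man_counts,
      manifestation_pct = percent_of(man_counts, n),
      numeric_summary = vapply(numvars, function(v) msd(sub[[v]]),
                               numeric(2)),
      lab_counts = vapply(lab_variables(), function(v) {
        vapply(lab_levels(), function(l) sum(sub[[v]] == l), numeric(1))
      }, numeric(3)),
      delivery_counts = vapply(delivery_levels(), function(l) {
        sum(sub$delivery_type == l)
      }, numeric(1)),
      live_births = live_births,
      fetal_losses = size - live_births,
      term = sum(sub$term == 1 & sub$live_birth == 1),
      preterm = sum(sub$term == 0 & sub$live_birth == 1),
      weight_mean = mean(lw), weight_sd = if (degenerate) 0 else stats::sd(lw),
      apgar_mean = mean(la), apgar_sd = if (degenerate) 0 else stats::sd(la)
    )
  })
  structure(profiles, class = "cluster_profiles", n_total = n)
}

#' Build minimal cluster profiles from a perinatal summary table
#'
#' Turns a per-cluster summary table (columns cluster, size, live_births,
#' fetal_losses, term, preterm, weight_mean, apgar_mean, ...) into profiles
#' carrying the fields the risk-tier rules need. Used to tier the published
#' per-cluster statistics of the reference cohort directly.
#'
#' @param summary A data.frame like [reference_perinatal_summary()].
#' @return A `cluster_profiles` object.
#' @export
profiles_from_summary <- function(summary) {
  profiles <- lapply(seq_len(nrow(summary)), function(i) {
    as.list(summary[i, , drop = FALSE])
  })
  structure(profiles, class = "cluster_profiles",
            n_total = sum(summary$size))
}

#' @export
print.cluster_profiles <- function(x, ...) {
  cat(sprintf("cluster_profiles: %d clusters, %d patients\n",
              length(x), attr(x, "n_total")))
  for (p in x) {
    cat(sprintf(
      "  cluster %d: n=%d, losses=%d, weight %.0f g, Apgar %.2f\n",
      p$cluster, p$size, p$fetal_losses, p$weight_mean, p$apgar_mean))
  }
  invisible(x)
}

#' Default thresholds of the risk-tier rules
#'
#' High risk: fetal-loss proportion >= `loss_high` OR mean 1-minute Apgar
#' < `apgar_high` OR mean newborn weight < `weight_high` g. Low risk:
#' loss proportion < `loss_high` AND mean Apgar >= `apgar_low` AND preterm
#' proportion (among live births) <= `preterm_low`. Otherwise moderate.
#'
#' @param loss_high,apgar_high,weight_high,apgar_low,preterm_low Numeric
#'   cutoffs (defaults 0.10, 7, 1500 g, 9.8, 0.45).
#' @return Named list of thresholds.
#' @export
risk_thresholds <- function(loss_high = 0.10, apgar_high = 7,
                            weight_high = 1500, apgar_low = 9.8,
                            preterm_low = 0.45) {
  list(loss_high = loss_high, apgar_high = apgar_high,
       weight_high = weight_high, apgar_low = apgar_low,
       preterm_low = preterm_low)
}

#' Assign a high/moderate/low risk tier to each cluster
#'
#' Applies the threshold rules of [risk_thresholds()] with precedence
#' high > low > moderate (the fallback), recording the rule that fired.
#'
#' @param profiles A `cluster_profiles` object.
#' @param thresholds Tier cutoffs, from [risk_thresholds()].
#' @return A `risk_tier_map` data.frame: cluster, tier, rule, and the
#'   quantities the rules used; attribute `"thresholds"` echoes the cutoffs.
#' @export
assign_risk_tiers <- function(profiles, thresholds = risk_thresholds()) {
  stopifnot(inherits(profiles, "cluster_profiles"))
  if (!length(profiles)) stop("no profiles", call. = FALSE)
  th <- thresholds
  rows <- lapply(profiles, function(p) {
    need <- c("size", "fetal_losses", "live_births", "preterm",
              "weight_mean", "apgar_mean")
    if (!all(need %in% names(p))) {
      stop("profile missing perinatal fields", call. = FALSE)
    }
    loss_prop <- p$fetal_losses / p$size
    preterm_prop <- if (p$live_births > 0) p$preterm / p$live_births else 1
    if (loss_prop >= th$loss_high) {
      tier <- "high"; rule <- sprintf("fetal-loss proportion %.3f >= %.2f",
                                      loss_prop, th$loss_high)
    } else if (p$apgar_mean < th$apgar_high) {
      tier <- "high"; rule <- sprintf("mean Apgar %.2f < %g",
                                      p$apgar_mean, th$apgar_high)
    } else if (p$weight_mean < th$weight_high) {
      tier <- "high"; rule <- sprintf("mean weight %.0f g < %g g",
                                      p$weight_mean, th$weight_high)
    } else if (p$apgar_mean >= th$apgar_low &&
               preterm_prop <= th$preterm_low) {
      tier <- "low"
      rule <- sprintf("Apgar %.2f >= %g and preterm proportion %.3f <= %.2f",
                      p$apgar_mean, th$apgar_low, preterm_prop,
                      th$preterm_low)
    } else {
      tier <- "moderate"; rule <- "fallback: neither high nor low rule fired"
    }
    data.frame(cluster = p$cluster, tier = tier, rule = rule,
               loss_prop = loss_prop, preterm_prop = preterm_prop,
               apgar_mean = p$apgar_mean, weight_mean = p$weight_mean,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "thresholds") <- th
  class(out) <- c("risk_tier_map", "data.frame")
  out
}

tier_colors <- function() c(high = "red", moderate = "yellow", low = "green")

#' Export the risk-assessment chart data
#'
#' Emits a machine-readable chart specification: one block per tier (color,
#' member clusters, manifestations ranked by pooled frequency, expected
#' perinatal outcome summary) plus, when an assignment is supplied, a
#' patient-placement record (patient -> cluster -> tier) supporting
#' comparison of a patient's present and previous chart locations.
#'
#' @param profiles A `cluster_profiles` object (from [profile_clusters()],
#'   so manifestation counts are available).
#' @param tiers A `risk_tier_map` from [assign_risk_tiers()].
#' @param assignment Optional `cluster_assignment` for patient placements.
#' @param patient_ids Optional character vector matching `assignment`.
#' @param path Optional JSON output path.
#' @return The chart data as a list (invisibly written to `path` if given).
#' @export
export_chart_data <- function(profiles, tiers, assignment = NULL,
                              patient_ids = NULL, path = NULL) {
  stopifnot(inherits(profiles, "cluster_profiles"),
            inherits(tiers, "risk_tier_map"))
  chart <- list(tiers = list(), thresholds = attr(tiers, "thresholds"))
  mn <- manifestation_names()
  for (tier in c("high", "moderate", "low")) {
    members <- tiers$cluster[tiers$tier == tier]
    if (!length(members)) next
    pr <- profiles[vapply(profiles, function(p) p$cluster, numeric(1)) %in%
                     members]
    man <- NULL
    if (all(vapply(pr, function(p) "manifestation_counts" %in% names(p),
                   logical(1)))) {
      pooled <- Reduce(`+`, lapply(pr, `[[`, "manifestation_counts"))
      ord <- order(-pooled, names(pooled))
      keep <- pooled[ord] > 0
      man <- data.frame(indicator = names(pooled)[ord][keep],
                        manifestation = unname(mn[names(pooled)[ord][keep]]),
                        count = unname(pooled[ord][keep]),
                        stringsAsFactors = FALSE)
    }
    sizes <- vapply(pr, `[[`, numeric(1), "size")
    chart$tiers[[tier]] <- list(
      color = unname(tier_colors()[tier]),
      clusters = as.integer(members),
      patients = sum(sizes),
      manifestations = man,
      perinatal = list(
        fetal_losses = sum(vapply(pr, `[[`, numeric(1), "fetal_losses")),
        preterm = sum(vapply(pr, `[[`, numeric(1), "preterm")),
        term = sum(vapply(pr, `[[`, numeric(1), "term")),
        mean_weight_g = sum(vapply(pr, function(p) p$weight_mean * p$size,
                                   numeric(1))) / sum(sizes),
        mean_apgar = sum(vapply(pr, function(p) p$apgar_mean * p$size,
                                numeric(1))) / sum(sizes)))
  }
  if (!is.null(assignment)) {
    tier_of <- stats::setNames(tiers$tier, tiers$cluster)
    chart$placements <- data.frame(
      patient_id = if (is.null(patient_ids)) {
        sprintf("P%04d", seq_along(assignment$cluster))
      } else patient_ids,
      cluster = assignment$cluster,
      tier = unname(tier_of[as.character(assignment$cluster)]),
      stringsAsFactors = FALSE)
  }
  if (!is.null(path)) {
    jsonlite::write_json(chart, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(chart)
}

#' Read a risk-assessment chart file
#'
#' @param path Path to a JSON file written by [export_chart_data()].
#' @return The chart data as a list.
#' @export
read_chart_data <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
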