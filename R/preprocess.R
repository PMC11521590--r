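## Preprocessing: mode/mean imputation, outlier screening, min-max scaling.

categorical_csv_columns <- function() {
  c("urinary_protein_grade", lab_variables(), "delivery_type")
}

#' Impute missing cohort values by mode (categorical) and mean (numeric)
#'
#' Fills every missing categorical cell with the variable's modal label
#' among observed values and every missing numeric cell with the variable's
#' observed mean. Mode ties are broken deterministically by the fixed label
#' order L < N < H (CS < FD < ND for delivery; dipstick grades in increasing
#' order), and any tie-break applied is recorded in the returned log.
#'
#' @param cohort An `sle_cohort`.
#' @return The imputed cohort; attribute `"imputation_log"` is a data.frame
#'   recording each imputed variable, the fill value, the number of cells
#'   filled and whether a mode tie was broken.
#' @export
impute_missing <- function(cohort) {
  stopifnot(inherits(cohort, "sle_cohort"))
  df <- cohort$data
  log <- list()
  level_order <- list(urinary_protein_grade = dipstick_grades(),
                      delivery_type = delivery_levels())
  for (v in lab_variables()) level_order[[v]] <- lab_levels()

  for (v in setdiff(cohort_columns(), "patient_id")) {
    nmiss <- sum(is.na(df[[v]]))
    if (nmiss == 0) next
    obs <- df[[v]][!is.na(df[[v]])]
    if (!length(obs)) {
      stop("cannot impute '", v, "': no observed values", call. = FALSE)
    }
    if (v %in% categorical_csv_columns()) {
      lev <- intersect(level_order[[v]], unique(obs))
      counts <- vapply(lev, function(l) sum(obs == l), numeric(1))
      top <- lev[counts == max(counts)]
      fill <- top[1]  # first in fixed label order
      tie <- length(top) > 1
    } else {
      fill <- mean(obs)
      tie <- FALSE
    }
    df[[v]][is.na(df[[v]])] <- fill
    log[[length(log) + 1]] <- data.frame(
      variable = v, fill = as.character(fill), n_filled = nmiss,
      mode_tie_broken = tie, stringsAsFactors = FALSE)
  }
  cohort$data <- df
  attr(cohort, "imputation_log") <- if (length(log)) {
    do.call(rbind, log)
  } else {
    data.frame(variable = character(0), fill = character(0),
               n_filled = integer(0), mode_tie_broken = logical(0))
  }
  cohort
}

#' Screen numeric attributes for gross outliers
#'
#' Flags values lying outside median +/- `k` x IQR of their variable.
#' Constant variables (zero IQR) flag nothing. The default action is
#' flag-only; with `action = "remove"` the flagged patients are dropped.
#'
#' @param cohort An `sle_cohort`.
#' @param k Multiplier of the IQR (default 3).
#' @param action `"flag"` (default) or `"remove"`.
#' @return An `outlier_report`: data.frame `flagged` (patient_id, row,
#'   variable, value, rule), the `action` taken, and (when removing) the
#'   cleaned `cohort`.
#' @export
screen_outliers <- function(cohort, k = 3, action = c("flag", "remove")) {
  stopifnot(inherits(cohort, "sle_cohort"))
  action <- match.arg(action)
  df <- cohort$data
  flagged <- list()
  for (v in numeric_csv_columns()) {
    x <- df[[v]]
    obs <- x[!is.na(x)]
    if (length(obs) < 2) next
    iqr <- stats::IQR(obs)
    if (iqr == 0) next
    med <- stats::median(obs)
    lo <- med - k * iqr
    hi <- med + k * iqr
    bad <- which(!is.na(x) & (x < lo | x > hi))
    if (length(bad)) {
      flagged[[length(flagged) + 1]] <- data.frame(
        patient_id = df$patient_id[bad], row = bad, variable = v,
        value = x[bad],
        rule = sprintf("outside median +/- %g x IQR [%.4g, %.4g]", k, lo, hi),
        stringsAsFactors = FALSE)
    }
  }
  flagged <- if (length(flagged)) {
    out <- do.call(rbind, flagged)
    out <- out[order(out$row, out$variable), , drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    data.frame(patient_id = character(0), row = integer(0),
               variable = character(0), value = numeric(0),
               rule = character(0), stringsAsFactors = FALSE)
  }
  res <- list(flagged = flagged, action = action)
  if (action == "remove" && nrow(flagged)) {
    keep <- setdiff(seq_len(nrow(df)), unique(flagged$row))
    res$cohort <- as_sle_cohort(df[keep, , drop = FALSE])
  } else {
    res$cohort <- cohort
  }
  structure(res, class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("outlier screen: %d value(s) flagged (action: %s)\n",
              nrow(x$flagged), x$action))
  if (nrow(x$flagged)) print(utils::head(x$flagged, 10))
  invisible(x)
}

#' Normalize a feature matrix for clustering
#'
#' Applies the min-max map per column to the raw numeric attributes (their
#' units and ranges are arbitrary: years, days, grams, mg/dl), while the
#' quantified categorical columns are left on their common F scale. The F
#' scores are already commensurable across columns by construction -- each
#' lies in [0, sum of manifestation prevalences], about [0, 1] for this
#' cohort -- and per-column stretching would amplify the tiny differences
#' between pooled label scores into full-range noise.
#'
#' @param features Matrix from [build_feature_matrix()] (its `"provenance"`
#'   attribute marks numeric vs quantified columns; columns without
#'   provenance are treated as numeric).
#' @return List with `matrix` and `params` as in [minmax_normalize()];
#'   quantified columns carry identity parameters (min 0, max 1).
#' @export
normalize_features <- function(features) {
  prov <- attr(features, "provenance")
  if (is.null(prov)) prov <- rep("numeric", ncol(features))
  x <- as.matrix(features)
  if (!all(is.finite(x))) stop("non-finite values in feature matrix",
                               call. = FALSE)
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  quant <- prov == "quantified"
  mins[quant] <- 0
  maxs[quant] <- 1
  params <- structure(list(min = mins, max = maxs,
                           constant = maxs == mins), class = "normalization_params")
  minmax_normalize(x, params)
}

#' Min-max normalize a feature matrix to [0, 1]
#'
#' Rescales each column by x' = (x - x_min)/(x_max - x_min) using column
#' ranges from `params` when supplied (e.g. to reuse training ranges), else
#' from the matrix itself. Constant columns map to 0 and are flagged.
#'
#' @param x Numeric matrix (patients x features), all entries finite.
#' @param params Optional `normalization_params` from a previous call.
#' @return List with `matrix` (normalized) and `params`
#'   (`normalization_params`: per-feature `min`, `max`, `constant` flag).
#' @export
minmax_normalize <- function(x, params = NULL) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite values in feature matrix",
                               call. = FALSE)
  if (is.null(params)) {
    params <- structure(list(min = apply(x, 2, min), max = apply(x, 2, max)),
                        class = "normalization_params")
    params$constant <- params$max == params$min
  }
  rng <- params$max - params$min
  rng[params$constant] <- 1  # constant columns map to 0
  out <- sweep(sweep(x, 2, params$min, "-"), 2, rng, "/")
  out[, params$constant] <- 0
  list(matrix = out, params = params)
}
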