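## Quantification of categorical labels through co-occurrence with the
## binary base manifestations. The six nonbase labels are the pooled lab
## labels L/N/H (each patient contributes one occurrence per lab variable,
## 13 in all) and the delivery types CS/FD/ND (one occurrence per patient).
## Each label c receives the numeric score
##   F(c) = sum_j S(c, y_j) * ybar_j,
## where S is the Jaccard-style co-occurrence similarity
##   S(i, j) = O(i,j) / (O(i) + O(j) - O(i,j))
## and ybar_j is the cohort prevalence of manifestation y_j.

new_cooccurrence_counts <- function(O_ij, O_i, O_j, n) {
  stopifnot(all(O_ij >= 0), all(O_i >= 0), all(O_j >= 0))
  stopifnot(all(O_ij == round(O_ij)))
  structure(list(O_ij = O_ij, O_i = O_i, O_j = O_j, n = n),
            class = "cooccurrence_counts")
}

#' @export
print.cooccurrence_counts <- function(x, ...) {
  cat(sprintf("cooccurrence_counts: %d patients; label totals ", x$n))
  cat(paste(names(x$O_i), x$O_i, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Count label/manifestation co-occurrences in a cohort
#'
#' Computes O(i,j), O(i) and O(j) over the six nonbase labels and the 15
#' manifestations. Lab labels are pooled over all 13 lab variables, so each
#' patient contributes 13 label occurrences (hence sum of O over L/N/H is
#' 13n), while delivery labels contribute one per patient. O(i,j) counts,
#' over all (patient, variable) occurrences of label i, those whose patient
#' has manifestation j; O(j) is the number of patients with y_j = 1.
#'
#' @param cohort An imputed `sle_cohort` (no missing labels).
#' @return A `cooccurrence_counts` object.
#' @export
count_cooccurrence <- function(cohort) {
  stopifnot(inherits(cohort, "sle_cohort"))
  df <- cohort$data
  need <- c(lab_variables(), "delivery_type", manifestation_variables())
  if (any(vapply(df[need], anyNA, logical(1)))) {
    stop("cohort has missing labels or manifestations; impute first",
         call. = FALSE)
  }
  n <- nrow(df)
  Y <- as.matrix(df[, manifestation_variables()])  # n x 15 of 0/1
  labels <- label_order()
  ## per-patient occurrence count of each label (0..13 for L/N/H, 0/1 for
  ## delivery types)
  occ <- matrix(0, nrow = n, ncol = length(labels),
                dimnames = list(NULL, labels))
  for (v in lab_variables()) {
    for (l in lab_levels()) occ[, l] <- occ[, l] + (df[[v]] == l)
  }
  for (l in delivery_levels()) occ[, l] <- occ[, l] + (df$delivery_type == l)
  O_i <- colSums(occ)
  O_j <- colSums(Y)
  O_ij <- t(occ) %*% Y
  dimnames(O_ij) <- list(labels, manifestation_variables())
  ## pooling bounds: a label can co-occur with y_j at most O(i) times and at
  ## most 13 times per patient
  stopifnot(all(O_ij <= O_i), all(O_ij <= 13 * n))
  new_cooccurrence_counts(O_ij, O_i, O_j, n = n)
}

#' Co-occurrence similarity between nonbase labels and manifestations
#'
#' Elementwise Jaccard-style similarity
#' S(i,j) = O(i,j) / (O(i) + O(j) - O(i,j)). A zero denominator (both
#' totals zero) yields S = 0, read as absence of evidence of association.
#'
#' @param counts A `cooccurrence_counts` object.
#' @return Numeric 6 x 15 matrix of similarities in [0, 1].
#' @export
cooccurrence_similarity <- function(counts) {
  stopifnot(inherits(counts, "cooccurrence_counts"))
  if (any(counts$O_ij < 0) || any(counts$O_i < 0) || any(counts$O_j < 0)) {
    stop("negative counts", call. = FALSE)
  }
  denom <- outer(counts$O_i, counts$O_j, "+") - counts$O_ij
  S <- counts$O_ij / denom
  S[denom == 0] <- 0
  S
}

#' Cohort prevalence of each base manifestation
#'
#' @param cohort An imputed `sle_cohort`.
#' @return Named numeric vector ybar, ybar_j = (patients with y_j = 1)/n.
#' @export
base_prevalence <- function(cohort) {
  stopifnot(inherits(cohort, "sle_cohort"))
  n <- n_patients(cohort)
  if (n == 0) stop("empty cohort", call. = FALSE)
  colMeans(as.matrix(cohort$data[, manifestation_variables()]))
}

#' Quantify the categorical labels into numeric scores
#'
#' F(c) = sum over the 15 manifestations of S(c, y_j) * ybar_j: labels that
#' co-occur strongly with prevalent manifestations receive large scores.
#'
#' @param S Similarity matrix from [cooccurrence_similarity()].
#' @param ybar Prevalences from [base_prevalence()] on the same cohort.
#' @return Named numeric vector F over the labels L, N, H, CS, FD, ND.
#' @export
quantify_labels <- function(S, ybar) {
  if (ncol(S) != length(ybar)) stop("dimension mismatch", call. = FALSE)
  drop(S %*% ybar)
}

#' Within-group sum of squares and variance of the numeric attributes
#'
#' SSw = sum over the g numeric attributes of the sum of squared deviations
#' from the attribute mean; Vw = SSw/(n - g). Computed as a scale
#' diagnostic of the numeric block of the feature matrix.
#'
#' @param x Numeric matrix (patients x numeric attributes), typically the
#'   9-column numeric block.
#' @return List with `SSw`, `Vw`, `n`, `g`.
#' @export
within_group_stats <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  g <- ncol(x)
  if (n <= g) stop("need more observations than attributes (n > g)",
                   call. = FALSE)
  centered <- sweep(x, 2, colMeans(x), "-")
  SSw <- sum(centered^2)
  list(SSw = SSw, Vw = SSw / (n - g), n = n, g = g)
}

#' Names of the nine numeric feature columns
#' @return Character vector in canonical order (urinary protein appears as
#'   mg/dl converted from the dipstick grade).
#' @export
numeric_feature_names <- function() {
  c("disease_duration_y", "maternal_age_y", "urinary_protein_mg_dl",
    "gestational_age_d", "newborn_weight_g", "gravid", "para",
    "abortion", "live")
}

#' Assemble the all-numeric feature matrix
#'
#' Builds the patients x features matrix fed to the SOM: the 9 numeric
#' attributes (dipstick grade converted to mg/dl), the 13 lab columns with
#' each label replaced by its quantified score F(label), and the delivery
#' type likewise replaced. With `exclude_outcome_like = TRUE` the
#' outcome-adjacent columns (gestational age, newborn weight, delivery
#' type) are dropped.
#'
#' @param cohort An imputed `sle_cohort`.
#' @param F_c Quantified label scores from [quantify_labels()].
#' @param exclude_outcome_like Drop gestational age, newborn weight and
#'   delivery type (default `FALSE`, giving 23 columns).
#' @return Numeric matrix with attribute `"provenance"` marking each column
#'   `"numeric"` or `"quantified"`.
#' @export
build_feature_matrix <- function(cohort, F_c, exclude_outcome_like = FALSE) {
  stopifnot(inherits(cohort, "sle_cohort"))
  df <- cohort$data
  if (anyNA(df[, setdiff(cohort_columns(), "patient_id")])) {
    stop("cohort has missing values; impute first", call. = FALSE)
  }
  lookup <- function(lab) {
    if (any(!lab %in% names(F_c))) {
      stop("label without quantified value: ",
           paste(setdiff(unique(lab), names(F_c)), collapse = ", "),
           call. = FALSE)
    }
    unname(F_c[lab])
  }
  num <- cbind(
    disease_duration_y = df$disease_duration_y,
    maternal_age_y = df$maternal_age_y,
    urinary_protein_mg_dl = grade_to_mg_dl(df$urinary_protein_grade),
    gestational_age_d = df$gestational_age_d,
    newborn_weight_g = df$newborn_weight_g,
    gravid = df$gravid, para = df$para,
    abortion = df$abortion, live = df$live)
  quant <- vapply(lab_variables(), function(v) lookup(df[[v]]),
                  numeric(nrow(df)))
  if (nrow(df) == 1) quant <- matrix(quant, nrow = 1,
                                     dimnames = list(NULL, lab_variables()))
  out <- cbind(num, quant, delivery_type = lookup(df$delivery_type))
  prov <- c(rep("numeric", 9), rep("quantified", 14))
  names(prov) <- colnames(out)
  if (exclude_outcome_like) {
    drop_cols <- c("gestational_age_d", "newborn_weight_g", "delivery_type")
    out <- out[, setdiff(colnames(out), drop_cols), drop = FALSE]
    prov <- prov[colnames(out)]
  }
  rownames(out) <- df$patient_id
  attr(out, "provenance") <- prov
  out
}
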