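## Reference statistics of the original 119-patient pregnancy cohort of SLE
## patients (five clusters of 33/27/16/19/24). These printed summaries are
## the only patient-level information available: they parameterise the
## synthetic generator and serve as fixtures for the co-occurrence and
## risk-tier oracles.

#' Reference co-occurrence counts of the 119-patient cohort
#'
#' Published co-occurrence table between the six nonbase labels (pooled lab
#' labels L/N/H and delivery types CS/FD/ND) and the 15 binary maternal
#' manifestations y1..y15, together with the label totals O(i) (L 259, N 893,
#' H 395 pooled over 13 lab variables; CS 89, FD 22, ND 8) and manifestation
#' totals O(j).
#'
#' @return A list with `O_ij` (6 x 15 integer matrix), `O_i` (named length-6
#'   vector) and `O_j` (named length-15 vector), of class
#'   `cooccurrence_counts`.
#' @export
reference_cooccurrence_counts <- function() {
  O_ij <- matrix(c(
    4, 18,  52, 49, 20, 15,  7,  24, 9,  3,  7,  8,  5, 12,  26,
    35, 83, 133, 90, 18,  2, 21, 154, 21, 22, 11, 32, 15, 33, 223,
    13, 29,  88, 82, 14, 22, 11,  43, 9, 14,  8, 12,  6,  7,  37,
    1,  8,  15, 10,  2,  2,  3,  15, 3,  1,  1,  4,  2,  3,  18,
    3,  1,   6,  6,  2,  1,  0,   0, 0,  2,  0,  0,  0,  0,   1,
    0,  1,   0,  1,  0,  0,  0,   2, 0,  0,  1,  0,  0,  0,   3),
    nrow = 6, byrow = TRUE,
    dimnames = list(label_order(), manifestation_variables()))
  O_i <- stats::setNames(c(259, 893, 395, 89, 22, 8), label_order())
  O_j <- stats::setNames(c(4, 10, 21, 17, 4, 3, 3, 17, 3, 3, 2, 4, 2, 4, 22),
                         manifestation_variables())
  new_cooccurrence_counts(O_ij, O_i, O_j, n = 119L)
}

#' Reference per-cluster summaries of the 119-patient cohort
#'
#' The published per-cluster perinatal outcome counts and summary statistics:
#' cluster sizes, live births and fetal losses, term/preterm counts among
#' live births, newborn weight and first-minute Apgar (mean, SD). Used as a
#' fixture for the risk-tier rules and as generator defaults.
#'
#' @return A data.frame with one row per cluster.
#' @export
reference_perinatal_summary <- function() {
  data.frame(
    cluster      = 1:5,
    size         = c(33, 27, 16, 19, 24),
    live_births  = c(12, 27, 16, 19, 24),
    fetal_losses = c(21,  0,  0,  0,  0),
    term         = c( 3, 16,  8, 11, 21),
    preterm      = c( 9, 11,  8,  8,  3),
    weight_mean  = c(952, 2818, 2419, 2823, 2952),
    weight_sd    = c(846,  810,  505,  456,  623),
    apgar_mean   = c(2.82, 9.59, 9.69, 9.95, 9.92),
    apgar_sd     = c(3.96, 1.01, 0.87, 0.23, 0.41)
  )
}

#' Reference cohort-level outcome counts of the 119-patient cohort
#'
#' Cohort-wide counts behind the published outcome percentages: fetal losses
#' (21, all in the high-risk cluster), preterm births in the moderate-risk
#' clusters (19), term births in the low-risk clusters (32), total preterm
#' (39) and term (59) labors, patients with no manifestation (22) and with
#' preeclampsia (21).
#'
#' @return Named integer vector with element `n` = 119.
#' @export
reference_outcome_counts <- function() {
  c(n = 119L, fetal_loss = 21L, preterm_moderate = 19L, term_low = 32L,
    preterm_total = 39L, term_total = 59L,
    no_manifestation = 22L, preeclampsia = 21L)
}

## per-cluster generator parameters: numeric attributes (mean, sd),
## lab-label counts, delivery-type counts, manifestation counts,
## urinary-protein grade counts
reference_numeric_params <- function() {
  list(
    disease_duration_y = list(mean = c(4.84, 4.89, 4.71, 4.79, 4.14),
                              sd   = c(4.86, 3.40, 4.27, 3.38, 3.73)),
    maternal_age_y     = list(mean = c(28.94, 31.11, 25.81, 29.90, 29.29),
                              sd   = c(4.51, 3.77, 4.37, 3.20, 2.07)),
    gestational_age_d  = list(mean = c(178.40, 258.74, 254.00, 257.32, 268.92),
                              sd   = c(65.60, 17.11, 17.92, 14.63, 10.72)),
    gravid             = list(mean = c(2.09, 2.59, 1.13, 3.05, 1.00),
                              sd   = c(0.98, 0.69, 0.34, 1.27, 0.00)),
    para               = list(mean = c(0.94, 2.00, 0.94, 1.26, 1.00),
                              sd   = c(0.56, 0.00, 0.25, 0.45, 0.00)),
    abortion           = list(mean = c(1.33, 0.59, 0.13, 1.79, 0.00),
                              sd   = c(0.99, 0.69, 0.34, 1.08, 0.00)),
    live               = list(mean = c(0.52, 2.00, 0.94, 1.21, 1.04),
                              sd   = c(0.57, 0.28, 0.25, 0.42, 0.20))
  )
}

## rows L/N/H, columns = the 13 lab variables; published per-cluster label
## counts (a few columns do not sum to the cluster size in the source
## registry; they are used as proportions)
reference_lab_counts <- function() {
  labs <- lab_variables()
  mk <- function(l, n, h) {
    matrix(c(l, n, h), nrow = 3, byrow = TRUE,
           dimnames = list(lab_levels(), labs))
  }
  list(
    mk(c(0, 0, 0, 0, 0, 6, 5, 15, 11, 15, 13, 15, 5),
       c(9, 5, 20, 19, 10, 12, 23, 17, 20, 17, 20, 18, 14),
       c(23, 28, 13, 14, 23, 15, 5, 1, 1, 1, 0, 0, 14)),
    mk(c(0, 1, 0, 0, 0, 4, 5, 6, 5, 16, 4, 11, 0),
       c(18, 9, 23, 17, 13, 15, 9, 21, 22, 11, 23, 16, 16),
       c(9, 17, 4, 10, 14, 8, 3, 0, 0, 0, 0, 0, 11)),
    mk(c(0, 0, 0, 0, 0, 3, 2, 6, 5, 8, 2, 16, 0),
       c(5, 3, 13, 10, 4, 7, 13, 9, 10, 8, 14, 10, 9),
       c(11, 13, 3, 6, 12, 6, 1, 1, 1, 0, 0, 0, 7)),
    mk(c(0, 0, 0, 0, 0, 5, 2, 5, 5, 14, 6, 10, 2),
       c(8, 8, 18, 10, 9, 9, 16, 9, 13, 5, 13, 9, 13),
       c(11, 11, 1, 9, 10, 5, 1, 5, 1, 0, 0, 0, 4)),
    mk(c(0, 0, 0, 0, 0, 0, 2, 5, 6, 14, 1, 11, 3),
       c(19, 8, 24, 17, 12, 17, 21, 19, 16, 10, 21, 13, 13),
       c(5, 16, 0, 7, 12, 7, 1, 0, 2, 0, 2, 0, 8))
  )
}

## per-cluster delivery-type counts (CS, FD, ND); the FD column conflicts
## with the perinatal fetal-loss counts in the source (see generator docs)
reference_delivery_counts <- function() {
  m <- matrix(c(12, 20, 1,
                22,  1, 4,
                15,  1, 0,
                17,  0, 2,
                23,  0, 1),
              nrow = 5, byrow = TRUE,
              dimnames = list(NULL, delivery_levels()))
  m
}

## per-cluster manifestation counts, rows y1..y15, columns clusters 1..5
reference_manifestation_counts <- function() {
  matrix(c(
    3, 1, 0, 0, 0,
    2, 3, 1, 1, 3,
    10, 4, 5, 2, 0,
    8, 3, 3, 3, 0,
    2, 0, 1, 0, 1,
    2, 1, 0, 0, 0,
    0, 3, 0, 0, 0,
    1, 5, 2, 7, 2,
    1, 1, 0, 1, 0,
    2, 0, 1, 0, 0,
    0, 0, 0, 1, 1,
    0, 0, 2, 1, 1,
    0, 1, 0, 0, 1,
    0, 0, 0, 1, 3,
    2, 5, 1, 2, 12),
    nrow = 15, byrow = TRUE,
    dimnames = list(manifestation_variables(), paste0("cluster", 1:5)))
}

## per-cluster urinary-protein dipstick grade counts
## rows negative/trace/1+/2+/3+/4+, columns clusters 1..5
reference_protein_counts <- function() {
  matrix(c(
    7, 14, 4, 11, 18,
    0,  0, 0,  0,  0,
    5,  5, 2,  3,  6,
    8,  4, 5,  5,  0,
    11, 4, 5,  0,  0,
    2,  0, 0,  0,  0),
    nrow = 6, byrow = TRUE,
    dimnames = list(dipstick_grades(), paste0("cluster", 1:5)))
}

#' Default missingness pattern of the reference cohort
#'
#' Number of patients with a missing value per serological variable:
#' dsDNA and ANA 5 each, APL 7, SSA and SSB 4 each.
#'
#' @return Named integer vector.
#' @export
reference_missingness <- function() {
  c(dsDNA = 5L, ANA = 5L, APL = 7L, SSA = 4L, SSB = 4L)
}
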