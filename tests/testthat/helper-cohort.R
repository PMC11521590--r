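# Fixture builders used across the suite.

# a minimal hand-written cohort of n patients; all labs "N", delivery CS,
# no manifestations except y15, live term births
mini_cohort <- function(n = 3) {
  df <- data.frame(patient_id = sprintf("M%02d", seq_len(n)),
                   disease_duration_y = seq_len(n),
                   maternal_age_y = 25 + seq_len(n),
                   urinary_protein_grade = "negative",
                   gestational_age_d = 260,
                   newborn_weight_g = 3000,
                   gravid = 2, para = 1, abortion = 0, live = 1,
                   stringsAsFactors = FALSE)
  for (v in c("dsDNA", "ANA", "APL", "CRP", "ESR", "SSA", "SSB",
              "C3", "C4", "HB", "PLT", "RBC", "WBC")) df[[v]] <- "N"
  df$delivery_type <- "CS"
  for (j in 1:15) df[[paste0("y", j)]] <- 0
  df$y15 <- 1
  df$live_birth <- 1
  df$term <- 1
  df$apgar_1min <- 10
  as_sle_cohort(df)
}

# independent nested-loop recount of the co-occurrence statistics; kept
# deliberately naive (patient-by-patient, variable-by-variable loops)
naive_cooccurrence <- function(cohort) {
  df <- cohort_data(cohort)
  labs <- c("dsDNA", "ANA", "APL", "CRP", "ESR", "SSA", "SSB",
            "C3", "C4", "HB", "PLT", "RBC", "WBC")
  labels <- c("L", "N", "H", "CS", "FD", "ND")
  ys <- paste0("y", 1:15)
  O_ij <- matrix(0, 6, 15, dimnames = list(labels, ys))
  O_i <- setNames(numeric(6), labels)
  O_j <- setNames(numeric(15), ys)
  for (p in seq_len(nrow(df))) {
    for (y in ys) if (df[[y]][p] == 1) O_j[y] <- O_j[y] + 1
    for (v in labs) {
      l <- df[[v]][p]
      O_i[l] <- O_i[l] + 1
      for (y in ys) if (df[[y]][p] == 1) O_ij[l, y] <- O_ij[l, y] + 1
    }
    d <- df$delivery_type[p]
    O_i[d] <- O_i[d] + 1
    for (y in ys) if (df[[y]][p] == 1) O_ij[d, y] <- O_ij[d, y] + 1
  }
  list(O_ij = O_ij, O_i = O_i, O_j = O_j)
}
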