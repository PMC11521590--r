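# random small cohort with arbitrary labels/manifestations
random_small_cohort <- function(n, seed) {
  withr::with_seed(seed, {
    coh <- mini_cohort(n)
    df <- cohort_data(coh)
    for (v in c("dsDNA", "ANA", "APL", "CRP", "ESR", "SSA", "SSB",
                "C3", "C4", "HB", "PLT", "RBC", "WBC")) {
      df[[v]] <- sample(c("L", "N", "H"), n, replace = TRUE)
    }
    df$delivery_type <- sample(c("CS", "FD", "ND"), n, replace = TRUE)
    for (j in 1:15) df[[paste0("y", j)]] <- rbinom(n, 1, runif(1, 0.05, 0.9))
    as_sle_cohort(df)
  })
}

test_that("co-occurrence counting matches a naive nested-loop recount", {
  # single-patient closed form: 13 pooled N occurrences, one delivery label
  one <- mini_cohort(1)
  cts <- count_cooccurrence(one)
  expect_identical(cts$O_i[["N"]], 13)
  expect_identical(cts$O_ij["N", "y15"], 13)
  expect_identical(cts$O_i[["CS"]], 1)
  expect_identical(cts$O_j[["y15"]], 1)

  for (s in 1:20) {
    coh <- random_small_cohort(n = sample(3:20, 1), seed = 1000 + s)
    fast <- count_cooccurrence(coh)
    slow <- naive_cooccurrence(coh)
    expect_identical(fast$O_ij, slow$O_ij)
    expect_identical(fast$O_i, slow$O_i)
    expect_identical(fast$O_j, slow$O_j)
  }

  expect_error(count_cooccurrence(inject_missingness(
    generate_cohort(cohort_parameters(), seed = 1)$cohort)), "impute")
})

test_that("similarity follows the Jaccard co-occurrence form", {
  ref <- reference_cooccurrence_counts()
  S <- cooccurrence_similarity(ref)
  # brute-force evaluation, element by element
  for (i in 1:6) for (j in 1:15) {
    o <- ref$O_ij[i, j]
    expect_equal(S[i, j], o / (ref$O_i[i] + ref$O_j[j] - o),
                 tolerance = 1e-15, ignore_attr = TRUE)
  }
  expect_equal(S["L", "y1"], 4 / 259, tolerance = 1e-12)
  expect_true(all(S >= 0 & S <= 1))
  expect_identical(S == 0, ref$O_ij == 0)

  # conventions and degenerate cases
  z <- ref
  z$O_ij[] <- 0; z$O_i[] <- 0; z$O_j[] <- 0
  expect_true(all(cooccurrence_similarity(z) == 0))
  p <- ref
  p$O_ij[] <- 0; p$O_ij[1, 1] <- 7; p$O_i[] <- 0; p$O_i[1] <- 7
  p$O_j[] <- 0; p$O_j[1] <- 7
  expect_identical(cooccurrence_similarity(p)[1, 1], 1)

  neg <- ref; neg$O_j[1] <- -1
  expect_error(cooccurrence_similarity(neg), "negative")
})

test_that("similarity is scale-free and monotone in co-occurrence", {
  ref <- reference_cooccurrence_counts()
  doubled <- ref
  doubled$O_ij <- 2 * ref$O_ij
  doubled$O_i <- 2 * ref$O_i
  doubled$O_j <- 2 * ref$O_j
  expect_equal(cooccurrence_similarity(doubled),
               cooccurrence_similarity(ref))

  bumped <- ref
  bumped$O_ij["L", "y3"] <- ref$O_ij["L", "y3"] + 1
  expect_gt(cooccurrence_similarity(bumped)["L", "y3"],
            cooccurrence_similarity(ref)["L", "y3"])
})

test_that("base prevalence and label quantification behave as defined", {
  coh <- mini_cohort(4)
  ybar <- base_prevalence(coh)
  expect_identical(ybar[["y15"]], 1)
  expect_identical(ybar[["y6"]], 0)
  expect_error(base_prevalence(as_sle_cohort(cohort_template())), "empty")

  # one-hot similarity returns the matched prevalence
  S <- matrix(0, 6, 15, dimnames = list(c("L", "N", "H", "CS", "FD", "ND"),
                                        paste0("y", 1:15)))
  S["H", "y3"] <- 1
  yb <- setNames(seq(0.01, 0.15, by = 0.01), paste0("y", 1:15))
  F_c <- quantify_labels(S, yb)
  expect_identical(F_c[["H"]], yb[["y3"]])
  expect_identical(F_c[["L"]], 0)
  expect_error(quantify_labels(S[, 1:10], yb), "dimension mismatch")
})

test_that("quantified reference labels match an independent brute force", {
  ref <- reference_cooccurrence_counts()
  S <- cooccurrence_similarity(ref)
  ybar <- ref$O_j / ref$n
  F_c <- quantify_labels(S, ybar)

  # independent summation over the five nonzero ND terms
  f_nd <- 0
  for (j in paste0("y", 1:15)) {
    o <- ref$O_ij["ND", j]
    if (o > 0) f_nd <- f_nd + o / (8 + ref$O_j[[j]] - o) * ref$O_j[[j]] / 119
  }
  expect_equal(F_c[["ND"]], f_nd, tolerance = 1e-12)
  expect_equal(F_c[["ND"]], 0.0457269, tolerance = 1e-6)

  # convex-combination bound: 0 <= F <= sum of prevalences
  expect_true(all(F_c >= 0 & F_c <= sum(ybar)))
})

test_that("within-group statistics match hand and brute-force values", {
  expect_identical(within_group_stats(cbind(c(0, 2)))$SSw, 2)
  expect_identical(within_group_stats(cbind(c(0, 2)))$Vw, 2)
  expect_identical(within_group_stats(matrix(5, 20, 3))$SSw, 0)

  withr::with_seed(77, {
    x <- matrix(rnorm(119 * 9, mean = 50, sd = 20), 119, 9)
  })
  got <- within_group_stats(x)
  ss <- 0
  for (k in 1:9) {
    m <- sum(x[, k]) / 119
    for (i in 1:119) ss <- ss + (x[i, k] - m)^2
  }
  expect_equal(got$SSw, ss, tolerance = 1e-9)
  expect_equal(got$Vw, ss / 110, tolerance = 1e-9)
  expect_error(within_group_stats(x[1:9, ]), "n > g")
})

test_that("feature matrix substitutes quantified scores locally", {
  gen <- generate_cohort(cohort_parameters(), seed = 31)
  coh <- impute_missing(inject_missingness(gen$cohort, seed = 32))
  S <- cooccurrence_similarity(count_cooccurrence(coh))
  F_c <- quantify_labels(S, base_prevalence(coh))
  feats <- build_feature_matrix(coh, F_c)
  expect_identical(dim(feats), c(119L, 23L))
  expect_false(anyNA(feats))
  expect_identical(unname(table(attr(feats, "provenance"))["quantified"]), 14L)

  # all-N patient: the 13 lab features all equal F(N)
  df <- cohort_data(mini_cohort(2))
  df$disease_duration_y <- 4
  df$maternal_age_y <- 30
  df$ANA <- c("L", "H")
  two <- build_feature_matrix(as_sle_cohort(df), F_c)
  labs <- c("dsDNA", "APL", "CRP", "ESR", "SSA", "SSB",
            "C3", "C4", "HB", "PLT", "RBC", "WBC")
  expect_true(all(two[1, labs] == F_c[["N"]]))
  # locality: identical except ANA -> differ only in the ANA column
  diffs <- which(two[1, ] != two[2, ])
  expect_identical(names(diffs), "ANA")
  expect_equal(two[1, "ANA"] - two[2, "ANA"], F_c[["L"]] - F_c[["H"]])

  shrunk <- build_feature_matrix(coh, F_c, exclude_outcome_like = TRUE)
  expect_identical(ncol(shrunk), 20L)
  expect_false(any(c("gestational_age_d", "newborn_weight_g",
                     "delivery_type") %in% colnames(shrunk)))

  expect_error(build_feature_matrix(coh, F_c[1:3]), "without quantified value")
})
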