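fitted_toy_som <- function(seed = 3) {
  withr::with_seed(seed, {
    X <- rbind(matrix(runif(40, 0.0, 0.3), ncol = 2),
               matrix(runif(40, 0.7, 1.0), ncol = 2))
  })
  m <- train_som(init_som(som_grid(4, 4, epochs = 60), X, seed = seed), X)
  list(model = m, bmu = assign_bmu(m, X), X = X)
}

test_that("merge respects trivial k and the non-empty node bound", {
  f <- fitted_toy_som()
  n_ne <- sum(f$bmu$hits > 0)

  one <- merge_nodes(f$model, f$bmu, k = 1)
  expect_true(all(one$cluster == 1))

  each <- merge_nodes(f$model, f$bmu, k = n_ne)
  expect_identical(length(unique(each$cluster[f$bmu$hits > 0])), n_ne)

  expect_error(merge_nodes(f$model, f$bmu, k = 0), ">= 1")
  expect_error(merge_nodes(f$model, f$bmu, k = n_ne + 1), "exceeds")
})

test_that("two-blob codebooks split along the exhaustive Ward optimum", {
  # <= 10 nodes: compare against enumeration of every 2-partition by
  # hit-weighted within-cluster sum of squares
  withr::with_seed(9, {
    cb <- rbind(matrix(runif(10, 0, 0.2), ncol = 2),
                matrix(runif(10, 0.8, 1.0), ncol = 2))
    hits <- sample(1:5, 10, replace = TRUE)
  })
  model <- structure(list(codebook = cb, grid = som_grid(2, 5),
                          qe_log = numeric(0), trained = TRUE, seed = 1),
                     class = "batch_som")
  bmu <- list(bmu = rep(seq_len(10), hits), hits = hits)
  got <- merge_nodes(model, bmu, k = 2)

  wss <- function(assign) {
    sum(sapply(unique(assign), function(cl) {
      idx <- assign == cl
      ctr <- colSums(cb[idx, , drop = FALSE] * hits[idx]) / sum(hits[idx])
      sum(hits[idx] * rowSums(sweep(cb[idx, , drop = FALSE], 2, ctr)^2))
    }))
  }
  best <- NULL
  for (code in 1:(2^9 - 1)) {           # non-trivial bipartitions
    assign <- c(1L, as.integer(intToBits(code)[1:9]) + 1L)
    if (length(unique(assign)) == 2 && (is.null(best) || wss(assign) < best$w)) {
      best <- list(assign = assign, w = wss(assign))
    }
  }
  # same partition up to label swap
  agree <- table(got$cluster, best$assign)
  expect_identical(sum(agree > 0), 2L)
  expect_equal(wss(got$cluster), best$w)
})

test_that("empty nodes inherit the nearest non-empty node's cluster", {
  f <- fitted_toy_som()
  map <- merge_nodes(f$model, f$bmu, k = 2)
  expect_true(all(map$cluster >= 1 & map$cluster <= 2))
  empty <- which(f$bmu$hits == 0)
  ne <- which(f$bmu$hits > 0)
  if (length(empty)) {
    d <- as.matrix(dist(f$model$codebook))[empty, ne, drop = FALSE]
    nearest <- ne[apply(d, 1, which.min)]
    expect_identical(map$cluster[empty], map$cluster[nearest])
  }
})

test_that("davies-bouldin selection finds planted codebook blob counts", {
  mk_model <- function(centers, per = 6, spread = 0.005, seed = 1) {
    withr::with_seed(seed, {
      cb <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
        matrix(rnorm(per * 2, mean = centers[i, ], sd = spread),
               ncol = 2, byrow = TRUE)
      }))
    })
    n <- nrow(cb)
    model <- structure(list(codebook = cb, grid = som_grid(1, n),
                            qe_log = numeric(0), trained = TRUE, seed = 1),
                       class = "batch_som")
    list(model = model, bmu = list(bmu = seq_len(n), hits = rep(1L, n)))
  }
  five <- mk_model(cbind(c(0, 0.5, 1, 0, 1), c(0, 0.5, 1, 1, 0)))
  expect_identical(select_k(five$model, five$bmu, 2:10), 5L)

  two <- mk_model(cbind(c(0.1, 0.9), c(0.1, 0.9)))
  expect_identical(select_k(two$model, two$bmu, 2:6), 2L)

  expect_identical(select_k(five$model, five$bmu, 3), 3L)
  expect_error(select_k(five$model, five$bmu, integer(0)), "empty")
})

test_that("patient assignment is a relabeled size-ordered partition", {
  f <- fitted_toy_som()
  map <- merge_nodes(f$model, f$bmu, k = 2)
  a <- assign_patients(f$bmu, map)
  expect_identical(sum(a$counts), 40L)
  expect_identical(length(a$cluster), 40L)
  expect_false(is.unsorted(rev(a$counts)))   # decreasing sizes
  expect_identical(sort(unique(a$cluster)), seq_len(a$k))

  # all patients on one node -> single cluster
  solo <- list(bmu = rep(5L, 12), hits = tabulate(rep(5L, 12), 16))
  a1 <- assign_patients(solo, map)
  expect_identical(a1$k, 1L)
  expect_identical(a1$counts, 12L)

  bad <- list(bmu = 999L, hits = 1L)
  expect_error(assign_patients(bad, map), "unmapped")
})

test_that("agglomerative cuts are nested and counts are conserved", {
  f <- fitted_toy_som()
  k2 <- assign_patients(f$bmu, merge_nodes(f$model, f$bmu, k = 2))
  k4 <- assign_patients(f$bmu, merge_nodes(f$model, f$bmu, k = 4))
  # every k=4 cluster lies inside exactly one k=2 cluster
  for (cl in unique(k4$cluster)) {
    expect_identical(length(unique(k2$cluster[k4$cluster == cl])), 1L)
  }
})

test_that("kmeans merge strategy is deterministic and equivalent in form", {
  f <- fitted_toy_som()
  m1 <- merge_nodes(f$model, f$bmu, k = 2, strategy = "kmeans", seed = 4)
  m2 <- merge_nodes(f$model, f$bmu, k = 2, strategy = "kmeans", seed = 4)
  expect_identical(m1$cluster, m2$cluster)
  a <- assign_patients(f$bmu, m1)
  expect_identical(sum(a$counts), 40L)
  # blobs this separated: the flat and agglomerative routes agree
  aw <- assign_patients(f$bmu, merge_nodes(f$model, f$bmu, k = 2))
  expect_identical(sort(as.vector(table(a$cluster, aw$cluster))),
                   c(0L, 0L, 20L, 20L))
})

test_that("pipeline clusters recover well-separated planted structure", {
  skip_if_not_installed("mclust")
  # sharpened cohorts; permutation invariance of ARI checked alongside
  res <- suppressMessages(run_pipeline(pipeline_config(
    out_dir = withr::local_tempdir(), seed = 4,
    params = cohort_parameters(sd_scale = 0.25))))
  ari <- mclust::adjustedRandIndex(res$assignment$cluster, res$labels)
  expect_gt(ari, 0.6)
  perm <- c(3L, 5L, 1L, 2L, 4L)[res$assignment$cluster]
  expect_equal(mclust::adjustedRandIndex(perm, res$labels), ari)
})
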