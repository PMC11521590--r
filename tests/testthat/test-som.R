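toy_data <- function(n = 40, seed = 5) {
  withr::with_seed(seed, {
    cbind(x = runif(n), y = runif(n))
  })
}

test_that("initialization honours the grid and the seed", {
  X <- toy_data()
  m <- init_som(som_grid(12, 12), X, seed = 1, method = "sample")
  expect_identical(dim(m$codebook), c(144L, 2L))
  expect_identical(m$codebook,
                   init_som(som_grid(12, 12), X, seed = 1,
                            method = "sample")$codebook)
  expect_false(identical(m$codebook,
                         init_som(som_grid(12, 12), X, seed = 2,
                                  method = "sample")$codebook))

  # linear initialization is deterministic regardless of seed
  expect_identical(init_som(som_grid(4, 4), X, seed = 1)$codebook,
                   init_som(som_grid(4, 4), X, seed = 2)$codebook)
  expect_identical(dim(init_som(som_grid(4, 4), X)$codebook), c(16L, 2L))

  # degenerate 1x1 grid: the single node is a sampled data row
  one <- init_som(som_grid(1, 1), X, seed = 3, method = "sample")
  expect_true(any(apply(X, 1, function(r) all(r == one$codebook[1, ]))))

  # more nodes than rows: jittered sampling fallback stays finite
  big <- init_som(som_grid(12, 12), X[1:5, ], seed = 4, method = "sample")
  expect_true(all(is.finite(big$codebook)))

  expect_error(som_grid(radius_initial = 1, radius_final = 2),
               "non-increasing")
})

test_that("batch training collapses onto degenerate data", {
  X <- matrix(rep(c(0.3, 0.7), each = 25), 25, 2)
  m <- train_som(init_som(som_grid(3, 3, epochs = 50), X, seed = 1), X)
  expect_lt(quantization_error(m, X), 1e-20)
  expect_identical(length(m$qe_log), 50L)
})

test_that("zero-neighborhood batch update equals the k-means update", {
  # 6 distinct 1-D points, 1x6 grid, vanishing radius: each node must end
  # at the mean of its BMU set, here the points themselves
  X <- cbind(c(0.05, 0.2, 0.45, 0.6, 0.8, 0.95))
  g <- som_grid(1, 6, radius_initial = 1e-6, radius_final = 1e-6,
                epochs = 10, topology = "rectangular")
  m <- init_som(g, X, seed = 2, method = "sample")
  m <- train_som(m, X)
  a <- assign_bmu(m, X)
  for (node in unique(a$bmu)) {
    expect_equal(m$codebook[node, ],
                 colMeans(X[a$bmu == node, , drop = FALSE]),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  expect_lt(quantization_error(m, X), 1e-10)
})

test_that("two separated blobs are captured by a 2x1 grid", {
  withr::with_seed(11, {
    X <- rbind(matrix(rnorm(60, 0.2, 0.02), ncol = 2),
               matrix(rnorm(60, 0.8, 0.02), ncol = 2))
  })
  g <- som_grid(2, 1, radius_final = 0.05, epochs = 60)
  m <- train_som(init_som(g, X, seed = 12), X)
  a <- assign_bmu(m, X)
  expect_identical(sort(a$hits), c(30L, 30L))
  expect_lt(quantization_error(m, X), 0.02^2 * 2 * 3)  # within-blob scale
})

test_that("BMU assignment conserves hits and breaks ties low", {
  X <- toy_data(n = 119)
  m <- train_som(init_som(som_grid(12, 12, epochs = 30), X, seed = 6), X)
  a <- assign_bmu(m, X)
  expect_identical(sum(a$hits), 119L)
  expect_identical(tabulate(a$bmu, 144), a$hits)

  # exact-match lookup
  probe <- m$codebook[7, , drop = FALSE]
  expect_identical(assign_bmu(m, probe)$bmu, 7L)

  # engineered exact tie between nodes 3 and 9
  tie <- m
  tie$codebook[] <- 5
  tie$codebook[3, ] <- c(0, 0)
  tie$codebook[9, ] <- c(2, 0)
  expect_identical(assign_bmu(tie, cbind(1, 0))$bmu, 3L)

  expect_error(assign_bmu(m, cbind(1)), "dimension mismatch")
})

test_that("u-matrix equals a brute-force neighbor recomputation", {
  m <- init_som(som_grid(2, 1), toy_data(), seed = 1)
  m$codebook <- rbind(c(0, 0), c(0.6, 0.8))   # distance 1 apart
  expect_equal(u_matrix(m), c(1, 1))

  m$codebook <- rbind(c(0.4, 0.4), c(0.4, 0.4))
  expect_equal(u_matrix(m), c(0, 0))

  X <- toy_data(30, seed = 8)
  m3 <- train_som(init_som(som_grid(3, 3, epochs = 20), X, seed = 9), X)
  um <- u_matrix(m3)
  # recount: hexagonal 3x3 coordinates, neighbors at lattice distance 1
  r <- rep(0:2, each = 3); cc <- rep(0:2, times = 3)
  co <- cbind(cc + 0.5 * (r %% 2), r * sqrt(3) / 2)
  for (i in 1:9) {
    nb <- which(abs(sqrt(rowSums(sweep(co, 2, co[i, ])^2)) - 1) < 1e-6)
    d <- sapply(nb, function(j) {
      sqrt(sum((m3$codebook[i, ] - m3$codebook[j, ])^2))
    })
    expect_equal(um[i], mean(d))
  }
})

test_that("quantization error is the mean squared BMU distance", {
  m <- init_som(som_grid(1, 1, topology = "rectangular"), cbind(0), seed = 1)
  m$codebook[1, ] <- 0
  expect_identical(quantization_error(m, cbind(c(1, -1))), 1)
  expect_error(quantization_error(m, cbind(numeric(0))), "empty")
})

test_that("training reduces quantization error on cohort features", {
  for (s in 1:3) {
    gen <- generate_cohort(cohort_parameters(), seed = 55 + s)
    coh <- impute_missing(gen$cohort)
    F_c <- quantify_labels(
      cooccurrence_similarity(count_cooccurrence(coh)), base_prevalence(coh))
    X <- normalize_features(build_feature_matrix(coh, F_c))$matrix
    m0 <- init_som(som_grid(12, 12, epochs = 60), X)
    q0 <- quantization_error(m0, X)
    m1 <- train_som(m0, X)
    expect_lt(quantization_error(m1, X), q0)
    # sampled init on a grid smaller than the cohort also improves
    m2 <- init_som(som_grid(5, 5, radius_final = 0.2, epochs = 60), X,
                   seed = s, method = "sample")
    expect_lt(quantization_error(train_som(m2, X), X),
              quantization_error(m2, X))
  }
})

test_that("a batch fixed point is left unchanged by a further epoch", {
  # converged map: train long, then one extra epoch at the final radius
  X <- toy_data(30, seed = 13)
  g <- som_grid(3, 3, epochs = 200)
  m <- train_som(init_som(g, X, seed = 14), X)
  g1 <- som_grid(3, 3, radius_initial = g$radius_final,
                 radius_final = g$radius_final, epochs = 50)
  m$grid <- g1
  m2 <- train_som(m, X)   # drive to the fixed point at constant radius
  m2$grid <- som_grid(3, 3, radius_initial = g$radius_final,
                      radius_final = g$radius_final, epochs = 1)
  m3 <- train_som(m2, X)
  expect_lt(max(abs(m3$codebook - m2$codebook)), 1e-12)
})

test_that("lattice-adjacent nodes respond to more similar inputs", {
  # 1-D gradient data: codebook distances should grow with lattice distance
  X <- cbind(seq(0, 1, length.out = 60))
  g <- som_grid(1, 8, topology = "rectangular", epochs = 100)
  m <- train_som(init_som(g, X, seed = 3), X)
  cb <- drop(m$codebook)
  d_adj <- mean(abs(diff(cb)))
  d_far <- mean(abs(outer(cb, cb, "-"))[abs(outer(1:8, 1:8, "-")) > 1])
  expect_lt(d_adj, d_far)
})
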