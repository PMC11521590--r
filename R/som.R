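## Batch-trained self-organizing map. A rows x cols lattice of codebook
## vectors ("miniclusters") is fitted to the normalized feature matrix: per
## epoch every node is replaced by the Gaussian-neighborhood-weighted mean
## of all data points, with the neighborhood radius shrinking linearly over
## the epoch schedule. Performance is measured as mean squared distance of
## the patients to their best-matching unit (BMU).

#' Grid specification for a self-organizing map
#'
#' @param rows,cols Lattice dimensions (default 12 x 12 = 144 miniclusters).
#' @param topology `"hexagonal"` (default) or `"rectangular"` node layout.
#' @param radius_initial Starting neighborhood radius; default
#'   `max(rows, cols)/2`.
#' @param radius_final Final radius (default 1, capped at the initial
#'   radius); the schedule decays linearly and must be non-increasing.
#' @param epochs Number of batch epochs (default 200).
#' @return A `som_grid` list.
#' @export
som_grid <- function(rows = 12, cols = 12,
                     topology = c("hexagonal", "rectangular"),
                     radius_initial = max(rows, cols) / 2,
                     radius_final = min(1, radius_initial), epochs = 200) {
  topology <- match.arg(topology)
  stopifnot(rows >= 1, cols >= 1, epochs >= 1)
  if (radius_final > radius_initial) {
    stop("radius schedule must be non-increasing", call. = FALSE)
  }
  structure(list(rows = rows, cols = cols, topology = topology,
                 radius_initial = radius_initial,
                 radius_final = radius_final, epochs = epochs),
            class = "som_grid")
}

## planar coordinates of the lattice nodes, row-major node order; odd rows
## of a hexagonal lattice are offset by half a unit
lattice_coords <- function(grid) {
  r <- rep(seq_len(grid$rows), each = grid$cols) - 1
  c <- rep(seq_len(grid$cols), times = grid$rows) - 1
  if (grid$topology == "hexagonal") {
    cbind(x = c + 0.5 * (r %% 2), y = r * sqrt(3) / 2)
  } else {
    cbind(x = c, y = r)
  }
}

## squared Euclidean distances between the rows of x and the rows of y
cross_dist2 <- function(x, y) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(y))) +
    outer(rep(1, nrow(x)), rowSums(y^2)) - 2 * x %*% t(y)
  pmax(d2, 0)
}

#' Initialize a SOM codebook
#'
#' The default linear initialization spreads the codebook over the plane of
#' the top two principal components of the data (deterministic, the usual
#' starting point for batch training). `method = "sample"` instead draws
#' random data rows; when the grid has more nodes than data rows that
#' sample is drawn with replacement and jittered.
#'
#' @param grid A [som_grid()].
#' @param data Numeric matrix (patients x features), normalized to [0, 1].
#' @param seed Integer seed (used by the sampling method).
#' @param method `"linear"` (default) or `"sample"`.
#' @return A `batch_som` model (codebook, grid, empty training log).
#' @export
init_som <- function(grid, data, seed = 1, method = c("linear", "sample")) {
  stopifnot(inherits(grid, "som_grid"))
  method <- match.arg(method)
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("non-finite data", call. = FALSE)
  m <- grid$rows * grid$cols
  codebook <- with_local_seed(seed, {
    if (method == "linear") {
      pc <- stats::prcomp(data, center = TRUE, rank. = 2)
      co <- lattice_coords(grid)
      u <- if (grid$cols > 1) (co[, 1] - min(co[, 1])) /
        (max(co[, 1]) - min(co[, 1])) - 0.5 else rep(0, m)
      v <- if (grid$rows > 1) (co[, 2] - min(co[, 2])) /
        (max(co[, 2]) - min(co[, 2])) - 0.5 else rep(0, m)
      sd1 <- if (ncol(pc$rotation) >= 1) 2 * stats::sd(pc$x[, 1]) else 0
      sd2 <- if (ncol(pc$rotation) >= 2) 2 * stats::sd(pc$x[, 2]) else 0
      cb <- matrix(rep(colMeans(data), each = m), nrow = m)
      if (isTRUE(sd1 > 0)) cb <- cb + (u * sd1) %*% t(pc$rotation[, 1])
      if (isTRUE(sd2 > 0)) cb <- cb + (v * sd2) %*% t(pc$rotation[, 2])
      cb
    } else if (m <= nrow(unique(data))) {
      data[sample.int(nrow(data), m), , drop = FALSE]
    } else {
      idx <- sample.int(nrow(data), m, replace = TRUE)
      data[idx, , drop = FALSE] +
        matrix(stats::rnorm(m * ncol(data), sd = 1e-4), nrow = m)
    }
  })
  dimnames(codebook) <- list(NULL, colnames(data))
  structure(list(codebook = codebook, grid = grid,
                 qe_log = numeric(0), trained = FALSE, seed = seed),
            class = "batch_som")
}

#' @export
print.batch_som <- function(x, ...) {
  g <- x$grid
  cat(sprintf("batch_som: %d x %d %s lattice (%d nodes), %d features, %s\n",
              g$rows, g$cols, g$topology, g$rows * g$cols,
              ncol(x$codebook),
              if (x$trained) sprintf("trained (%d epochs, final QE %.4g)",
                                     length(x$qe_log),
                                     utils::tail(x$qe_log, 1))
              else "untrained"))
  invisible(x)
}

#' Train a SOM in batch mode
#'
#' Runs the full epoch schedule: each epoch assigns every data point to its
#' BMU, then replaces each node's vector by the weighted mean of all data
#' points with Gaussian weights h = exp(-d_lattice^2 / (2 sigma^2)) between
#' the node and each point's BMU; sigma decays linearly from the initial to
#' the final radius. Nodes receiving zero total weight keep their previous
#' vector. The per-epoch quantization error is logged.
#'
#' @param model A `batch_som` from [init_som()].
#' @param data Numeric matrix with the codebook's column count.
#' @return The trained `batch_som`.
#' @export
train_som <- function(model, data) {
  stopifnot(inherits(model, "batch_som"))
  data <- as.matrix(data)
  if (nrow(data) == 0) stop("empty data", call. = FALSE)
  if (!all(is.finite(data))) stop("non-finite data", call. = FALSE)
  if (ncol(data) != ncol(model$codebook)) {
    stop("data column count does not match codebook", call. = FALSE)
  }
  grid <- model$grid
  co <- lattice_coords(grid)
  lat_d2 <- cross_dist2(co, co)
  epochs <- grid$epochs
  radius <- if (epochs == 1) grid$radius_initial else {
    grid$radius_initial +
      (grid$radius_final - grid$radius_initial) *
      (seq_len(epochs) - 1) / (epochs - 1)
  }
  cb <- model$codebook
  qe <- numeric(epochs)
  for (t in seq_len(epochs)) {
    d2 <- cross_dist2(data, cb)
    bmu <- max.col(-d2, ties.method = "first")
    sigma <- max(radius[t], 1e-8)
    h <- exp(-lat_d2 / (2 * sigma^2))  # m x m neighborhood kernel
    w <- h[, bmu, drop = FALSE]        # m x n weights
    den <- rowSums(w)
    num <- w %*% data
    upd <- den > 0
    cb[upd, ] <- num[upd, , drop = FALSE] / den[upd]
    qe[t] <- mean(rowSums((data - cb[max.col(-cross_dist2(data, cb),
                                             ties.method = "first"), ,
                                     drop = FALSE])^2))
  }
  model$codebook <- cb
  model$qe_log <- c(model$qe_log, qe)
  model$trained <- TRUE
  model
}

#' Best-matching units and node hit counts
#'
#' Assigns each data point to the node with the nearest codebook vector
#' (squared Euclidean distance; ties broken by the lowest node index).
#'
#' @param model A `batch_som`.
#' @param data Numeric matrix compatible with the codebook.
#' @return List with `bmu` (per-point node index) and `hits` (per-node
#'   counts, summing to `nrow(data)`).
#' @export
assign_bmu <- function(model, data) {
  stopifnot(inherits(model, "batch_som"))
  data <- as.matrix(data)
  if (ncol(data) != ncol(model$codebook)) {
    stop("dimension mismatch", call. = FALSE)
  }
  d2 <- cross_dist2(data, model$codebook)
  bmu <- max.col(-d2, ties.method = "first")
  m <- nrow(model$codebook)
  hits <- tabulate(bmu, nbins = m)
  list(bmu = bmu, hits = hits)
}

#' U-matrix of a SOM
#'
#' Per node, the mean Euclidean distance between its codebook vector and
#' those of its lattice-adjacent neighbors (6 for an interior hexagonal
#' node, fewer at edges). Large values mark cluster boundaries.
#'
#' @param model A `batch_som`.
#' @return Numeric vector of length rows x cols.
#' @export
u_matrix <- function(model) {
  stopifnot(inherits(model, "batch_som"))
  co <- lattice_coords(model$grid)
  lat_d <- sqrt(cross_dist2(co, co))
  adj <- abs(lat_d - 1) < 1e-6
  cb_d <- sqrt(cross_dist2(model$codebook, model$codebook))
  vapply(seq_len(nrow(co)), function(i) {
    nb <- which(adj[i, ])
    if (!length(nb)) 0 else mean(cb_d[i, nb])
  }, numeric(1))
}

#' Quantization error of a SOM on a data set
#'
#' Mean over data points of the squared Euclidean distance to the BMU (the
#' mean-square-error performance measure of the map).
#'
#' @param model A `batch_som`.
#' @param data Numeric matrix compatible with the codebook.
#' @return Non-negative scalar.
#' @export
quantization_error <- function(model, data) {
  data <- as.matrix(data)
  if (nrow(data) == 0) stop("empty data", call. = FALSE)
  a <- assign_bmu(model, data)
  mean(rowSums((data - model$codebook[a$bmu, , drop = FALSE])^2))
}
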