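## Two-level clustering: the trained SOM's miniclusters are merged into a
## small number of high-level patient clusters by hit-weighted Ward
## agglomeration of the codebook vectors, and each patient inherits the
## cluster of its BMU node.

#' Merge SOM miniclusters into high-level clusters
#'
#' Agglomerates the non-empty nodes (hits > 0) by Ward's criterion on the
#' codebook vectors, with each node weighted by its hit count. Empty nodes
#' inherit the cluster of the nearest non-empty node (ties broken by lowest
#' node index), so that every lattice node is colorable. Deterministic.
#'
#' @param model A trained `batch_som`.
#' @param bmu A BMU assignment from [assign_bmu()] (supplies hit counts).
#' @param k Number of high-level clusters; must not exceed the number of
#'   non-empty nodes.
#' @param strategy `"ward"` (default, hit-weighted agglomeration) or
#'   `"kmeans"` (hit-weighted k-means on the codebook, a flat alternative).
#' @param seed Seed for the k-means restarts (ignored for Ward).
#' @return A `node_cluster_map`: list with `cluster` (per-node index 1..k),
#'   `k`, `nonempty` (node indices) and, for Ward, the `hclust` tree.
#' @export
merge_nodes <- function(model, bmu, k = 5, strategy = c("ward", "kmeans"),
                        seed = 1) {
  stopifnot(inherits(model, "batch_som"))
  strategy <- match.arg(strategy)
  hits <- bmu$hits
  nonempty <- which(hits > 0)
  if (!length(nonempty)) stop("all nodes empty", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k > length(nonempty)) {
    stop("k exceeds number of non-empty nodes (", length(nonempty), ")",
         call. = FALSE)
  }
  cb <- model$codebook[nonempty, , drop = FALSE]
  hc <- NULL
  cl_ne <- if (length(nonempty) == 1) {
    1L
  } else if (strategy == "kmeans") {
    ## hit weighting by row replication; deterministic given seed
    rep_rows <- rep(seq_len(nrow(cb)), hits[nonempty])
    km <- with_local_seed(seed, stats::kmeans(cb[rep_rows, , drop = FALSE],
                                              centers = k, nstart = 25,
                                              iter.max = 100))
    km$cluster[match(seq_len(nrow(cb)), rep_rows)]
  } else {
    ## weighted Ward: squared Euclidean dissimilarities with node hit
    ## counts as member weights
    d2 <- stats::as.dist(cross_dist2(cb, cb))
    hc <- stats::hclust(d2, method = "ward.D", members = hits[nonempty])
    stats::cutree(hc, k = k)
  }
  cluster <- integer(nrow(model$codebook))
  cluster[nonempty] <- cl_ne
  empty <- which(hits == 0)
  if (length(empty)) {
    d2e <- cross_dist2(model$codebook[empty, , drop = FALSE], cb)
    nearest <- max.col(-d2e, ties.method = "first")
    cluster[empty] <- cl_ne[nearest]
  }
  structure(list(cluster = cluster, k = k, nonempty = nonempty, tree = hc),
            class = "node_cluster_map")
}

## hit-weighted Davies-Bouldin index of a node clustering
weighted_davies_bouldin <- function(codebook, hits, cluster) {
  ks <- sort(unique(cluster))
  cent <- t(vapply(ks, function(c) {
    idx <- cluster == c
    colSums(codebook[idx, , drop = FALSE] * hits[idx]) / sum(hits[idx])
  }, numeric(ncol(codebook))))
  scatter <- vapply(seq_along(ks), function(ci) {
    idx <- cluster == ks[ci]
    d <- sqrt(rowSums(sweep(codebook[idx, , drop = FALSE], 2,
                            cent[ci, ], "-")^2))
    sum(d * hits[idx]) / sum(hits[idx])
  }, numeric(1))
  M <- sqrt(cross_dist2(cent, cent))
  r <- vapply(seq_along(ks), function(i) {
    others <- setdiff(seq_along(ks), i)
    if (!length(others)) return(0)
    max((scatter[i] + scatter[others]) / M[i, others])
  }, numeric(1))
  mean(r)
}

#' Select the number of high-level clusters
#'
#' Evaluates each candidate k by the hit-weighted Davies-Bouldin index of
#' the merged node clustering (smaller is better) and returns the
#' minimizer; ties go to the smallest k. The default pipeline fixes k = 5;
#' this selector provides the data-driven alternative.
#'
#' @param model A trained `batch_som`.
#' @param bmu A BMU assignment from [assign_bmu()].
#' @param k_range Integer vector of candidate k (each >= 2 unless the range
#'   is a singleton, and <= number of non-empty nodes).
#' @return The selected k.
#' @export
select_k <- function(model, bmu, k_range = 2:10) {
  k_range <- sort(unique(as.integer(k_range)))
  if (!length(k_range)) stop("empty k range", call. = FALSE)
  if (length(k_range) == 1) return(k_range)
  hits <- bmu$hits
  nonempty <- which(hits > 0)
  k_range <- k_range[k_range <= length(nonempty)]
  if (!length(k_range)) stop("no feasible k in range", call. = FALSE)
  db <- vapply(k_range, function(k) {
    map <- merge_nodes(model, bmu, k)
    weighted_davies_bouldin(model$codebook[nonempty, , drop = FALSE],
                            hits[nonempty], map$cluster[nonempty])
  }, numeric(1))
  k_range[which.min(db)]  # which.min takes the first (smallest k) on ties
}

#' Assign patients to high-level clusters
#'
#' Each patient receives the cluster of its BMU node. Cluster indices are
#' relabeled to be contiguous from 1 with no empty clusters, ordered by
#' decreasing patient count (ties by first occurrence), so cluster 1 is
#' always the largest.
#'
#' @param bmu A BMU assignment from [assign_bmu()].
#' @param node_map A `node_cluster_map` from [merge_nodes()].
#' @return A `cluster_assignment`: list with `cluster` (per-patient index),
#'   `counts` (per-cluster sizes summing to n) and `k`.
#' @export
assign_patients <- function(bmu, node_map) {
  stopifnot(inherits(node_map, "node_cluster_map"))
  if (any(bmu$bmu > length(node_map$cluster))) {
    stop("BMU refers to unmapped node", call. = FALSE)
  }
  raw <- node_map$cluster[bmu$bmu]
  tab <- table(raw)
  ord <- order(-as.integer(tab), as.integer(names(tab)))
  relabel <- stats::setNames(seq_along(ord), names(tab)[ord])
  cluster <- unname(relabel[as.character(raw)])
  counts <- as.integer(table(cluster))
  structure(list(cluster = cluster, counts = counts, k = length(counts)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d patients in %d clusters (%s)\n",
              sum(x$counts), x$k, paste(x$counts, collapse = "/")))
  invisible(x)
}
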