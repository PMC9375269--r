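# Neighbour structures over a feature matrix: mini-groups (weakly connected
# components of the directed 1-nearest-neighbour graph) and mini-clusters
# (farthest-first seeded centers, nearest-center assignment). Both support
# Euclidean distance and correlation distance (1 - Pearson r).

#' Pairwise distance matrix under a metric
#'
#' Euclidean distance, or correlation distance defined as 1 minus the Pearson
#' correlation of the two feature vectors (range \[0, 2\]; 0 for perfectly
#' positively correlated vectors, hence invariant to positive affine
#' rescaling). For a zero-variance vector the correlation is undefined: its
#' distance to any other vector is defined as 1 (treated as uncorrelated),
#' except 0 to an identical vector.
#'
#' @param x Numeric matrix, one row per sample.
#' @param metric \code{"euclidean"} or \code{"pcc"}.
#' @return Symmetric n x n matrix with zero diagonal.
#' @export
feature_dist <- function(x, metric = c("euclidean", "pcc")) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  if (metric == "euclidean") {
    as.matrix(stats::dist(x))
  } else {
    v <- apply(x, 1L, stats::var)
    D <- 1 - suppressWarnings(stats::cor(t(x)))
    zv <- which(v == 0 | is.na(v))
    if (length(zv)) {
      for (i in zv) {
        same <- colSums(t(x) != x[i, ]) == 0L
        D[i, ] <- ifelse(same, 0, 1)
        D[, i] <- D[i, ]
      }
    }
    diag(D) <- 0
    D
  }
}

# Row-wise nearest neighbour indices from a distance matrix; self excluded,
# ties broken by smallest index.
.nn_from_dist <- function(D) {
  diag(D) <- Inf
  max.col(-D, ties.method = "first")
}

#' Nearest neighbour of a sample
#'
#' @param features Numeric matrix, one row per sample (n >= 2).
#' @param metric \code{"euclidean"} or \code{"pcc"}.
#' @param i Optional sample index; when omitted, the nearest neighbour of
#'   every sample is returned.
#' @return Integer index (or vector of indices) of the nearest other sample;
#'   ties broken by smallest index.
#' @export
nearest_neighbor <- function(features, metric = c("euclidean", "pcc"),
                             i = NULL) {
  features <- as.matrix(features)
  if (nrow(features) < 2L) stop("need at least 2 samples")
  nn <- .nn_from_dist(feature_dist(features, metric))
  if (is.null(i)) nn else nn[i]
}

# Union-find over the edges i -- nn(i); components relabelled 1..G in order
# of first appearance (so labels are deterministic).
.mg_labels <- function(D) {
  nn <- .nn_from_dist(D)
  n <- length(nn)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n)) {
    ri <- find(i)
    rj <- find(nn[i])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

.new_partition <- function(labels, method, metric, centers = NULL) {
  structure(list(labels = as.integer(labels),
                 method = method, metric = metric,
                 n_groups = max(labels), centers = centers),
            class = "sirna_partition")
}

#' @export
print.sirna_partition <- function(x, ...) {
  cat(sprintf("%s partition (%s distance): %d samples in %d groups\n",
              x$method, x$metric, length(x$labels), x$n_groups))
  invisible(x)
}

#' Export a partition as a data frame
#'
#' @param x A \code{sirna_partition}.
#' @param ids Optional sample identifiers (default the sample indices).
#' @param ... Unused.
#' @return Data frame with columns \code{sample_id}, \code{group_id},
#'   \code{method}.
#' @export
as.data.frame.sirna_partition <- function(x, ids = NULL, ...) {
  if (is.null(ids)) ids <- seq_along(x$labels)
  data.frame(sample_id = ids, group_id = x$labels, method = x$method,
             stringsAsFactors = FALSE)
}

#' Mini-group partition (MG algorithm)
#'
#' Places every sample in the same mini-group as its nearest neighbour: the
#' groups are the weakly connected components of the directed 1-NN graph
#' (edge from each sample to its nearest other sample), i.e. the minimal
#' sets closed under the nearest-neighbour relation. MG1 uses Euclidean
#' distance, MG2 correlation distance. Every group has at least 2 members.
#'
#' @param features Numeric matrix, one row per sample (n >= 2).
#' @param metric \code{"euclidean"} (MG1) or \code{"pcc"} (MG2).
#' @return A \code{sirna_partition} with contiguous group ids from 1.
#' @export
mg_partition <- function(features, metric = c("euclidean", "pcc")) {
  metric <- match.arg(metric)
  features <- as.matrix(features)
  if (nrow(features) < 2L) stop("need at least 2 samples")
  labels <- .mg_labels(feature_dist(features, metric))
  .new_partition(labels, if (metric == "euclidean") "MG1" else "MG2", metric)
}

# Farthest-first seeded clustering from a distance matrix. The first two
# centers realise the maximum pairwise distance (lexicographically smallest
# such pair); each further center maximises its minimum distance to the
# chosen centers (ties by smallest index). Samples go to their nearest
# center by smallest sample index; centers always belong to their own
# cluster, so exactly k clusters are non-empty.
.icc_labels <- function(D, k) {
  n <- nrow(D)
  if (k < 1L || k > n) stop("n_clusters must lie in 1..n")
  if (k == n) return(list(labels = seq_len(n), centers = seq_len(n)))
  if (k == 1L) {
    centers <- 1L
  } else {
    U <- D
    U[lower.tri(U, diag = TRUE)] <- -Inf
    mx <- max(U)
    cand <- which(U == mx, arr.ind = TRUE)
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    centers <- as.integer(cand[1L, ])
    mind <- pmin(D[, centers[1L]], D[, centers[2L]])
    while (length(centers) < k) {
      nxt <- which.max(replace(mind, centers, -Inf))
      centers <- c(centers, nxt)
      mind <- pmin(mind, D[, nxt])
    }
  }
  sc <- sort(centers)
  A <- D[, sc, drop = FALSE]
  assigned <- sc[max.col(-A, ties.method = "first")]
  assigned[sc] <- sc
  list(labels = match(assigned, sc), centers = sc)
}

#' Mini-cluster partition (Icc cluster)
#'
#' Farthest-point seeded clustering: the first two centers are the pair of
#' samples at maximum distance, each subsequent center is the sample whose
#' minimum distance to the chosen centers is largest, and the remaining
#' samples are assigned to their nearest center. Icc1 uses Euclidean
#' distance, Icc2 correlation distance. When used within the potency
#' pipeline the number of clusters is set to the training-set size.
#'
#' @param features Numeric matrix, one row per sample.
#' @param n_clusters Number of clusters, between 1 and n.
#' @param metric \code{"euclidean"} (Icc1) or \code{"pcc"} (Icc2).
#' @return A \code{sirna_partition}; group ids are contiguous from 1 in
#'   center sample-index order and exactly \code{n_clusters} groups are
#'   non-empty.
#' @export
icc_cluster <- function(features, n_clusters, metric = c("euclidean", "pcc")) {
  metric <- match.arg(metric)
  features <- as.matrix(features)
  res <- .icc_labels(feature_dist(features, metric), as.integer(n_clusters))
  p <- .new_partition(res$labels,
                      if (metric == "euclidean") "Icc1" else "Icc2",
                      metric, centers = res$centers)
  p$n_groups <- as.integer(n_clusters)
  p
}
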