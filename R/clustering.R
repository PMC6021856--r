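#' Mean-shift clustering
#'
#' Flat-kernel mode seeking, the standard formulation used by mainstream
#' toolkits: every point repeatedly moves to the mean of the points within
#' one bandwidth of it until convergence, and points whose modes coincide
#' (within one bandwidth) form one cluster. The default bandwidth is the
#' k-nearest-neighbour quantile heuristic: the average distance of a point
#' to its `round(n * bandwidth_quantile)`-th nearest neighbour. With
#' several habit modes of comparable size, a quantile reaching deep into a
#' mode's population merges adjacent modes; 0.2 keeps the kernel inside a
#' mode while still bridging day-to-day jitter.
#'
#' @param X Numeric matrix (points x dimensions).
#' @param bandwidth Kernel radius; `NULL` (default) uses the quantile
#'   heuristic.
#' @param bandwidth_quantile Neighbourhood quantile for the bandwidth
#'   estimate (default 0.2).
#' @param max_iter,tol Mode-seeking iteration controls.
#' @return List with `labels` (1-based, ordered by decreasing cluster
#'   size), `modes` (cluster x dim) and `bandwidth`.
#' @export
mean_shift <- function(X, bandwidth = NULL, bandwidth_quantile = 0.2,
                       max_iter = 300, tol = 1e-4) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) return(list(labels = rep(1L, n), modes = X, bandwidth = bandwidth))
  if (is.null(bandwidth)) {
    D <- as.matrix(dist(X))
    k <- min(n, max(2L, round(n * bandwidth_quantile)))
    bandwidth <- mean(apply(D, 1, function(r) sort(r)[k]))
  }
  if (!is.finite(bandwidth) || bandwidth <= 0) {
    warning("degenerate bandwidth (duplicate points); falling back to one cluster")
    return(list(labels = rep(1L, n),
                modes = matrix(colMeans(X), 1), bandwidth = bandwidth))
  }
  bw2 <- bandwidth^2
  Y <- X
  x2 <- rowSums(X^2)
  for (it in seq_len(max_iter)) {
    D2 <- outer(rowSums(Y^2), x2, "+") - 2 * Y %*% t(X)
    W <- (D2 <= bw2) * 1
    Ynew <- (W %*% X) / rowSums(W)
    shift <- sqrt(rowSums((Ynew - Y)^2))
    Y <- Ynew
    if (max(shift) < tol * bandwidth) break
  }
  # merge converged modes lying within one bandwidth of each other
  labels <- integer(n)
  modes <- NULL
  for (i in seq_len(n)) {
    assigned <- FALSE
    if (!is.null(modes)) {
      dd <- sqrt(rowSums(sweep(modes, 2, Y[i, ])^2))
      j <- which(dd < bandwidth)
      if (length(j) > 0) {
        labels[i] <- j[1]
        assigned <- TRUE
      }
    }
    if (!assigned) {
      modes <- rbind(modes, Y[i, , drop = FALSE])
      labels[i] <- nrow(modes)
    }
  }
  # relabel by decreasing cluster size
  sizes <- sort(table(labels), decreasing = TRUE)
  remap <- setNames(seq_along(sizes), names(sizes))
  labels <- as.integer(remap[as.character(labels)])
  ord <- as.integer(names(sizes))
  list(labels = labels, modes = modes[ord, , drop = FALSE], bandwidth = bandwidth)
}

cluster_metrics <- function(space, labels) {
  sil <- NA_real_
  if (length(unique(labels)) >= 2 && length(unique(labels)) < nrow(space)) {
    s <- cluster::silhouette(labels, dist(space))
    sil <- mean(s[, "sil_width"])
  }
  sizes <- sort(table(labels), decreasing = TRUE)
  coverage <- sum(head(sizes, 5)) / length(labels)
  list(silhouette = sil, coverage_top5 = coverage)
}

run_clustering <- function(space, algorithm, k, bandwidth, bandwidth_quantile,
                           seed) {
  set.seed(seed)
  if (algorithm == "mean_shift") {
    mean_shift(space, bandwidth = bandwidth,
               bandwidth_quantile = bandwidth_quantile)$labels
  } else if (algorithm == "kmeans") {
    if (is.null(k)) stop("k-means requires 'k'")
    kmeans(space, centers = k, nstart = 10)$cluster
  } else {
    if (is.null(k)) stop("spectral clustering requires 'k'")
    as.integer(kernlab::specc(as.matrix(space), centers = k))
  }
}

cluster_prototypes <- function(days, labels, prototype) {
  agg <- if (prototype == "median") {
    function(lst) apply(simplify2array(lst), c(1, 2), median)
  } else {
    function(lst) apply(simplify2array(lst), c(1, 2), mean)
  }
  lapply(sort(unique(labels)), function(cl) agg(days[labels == cl]))
}

#' Cluster autoencoder embeddings into habit groups
#'
#' Clusters per-day latent vectors (default: mean-shift with the quantile
#' bandwidth heuristic), then reports: cluster prototypes — the mean (or
#' median) day of each cluster in the *original* sensor space; the mean
#' silhouette width computed on the embedding with Euclidean distance (the
#' space this method "sees"); and the fraction of days covered by the five
#' largest clusters.
#'
#' @param emb An `embedding_set` from [encode_days()] (or a plain matrix).
#' @param days The original daily matrices, same order as the embedding
#'   (needed for prototypes; optional).
#' @param algorithm `"mean_shift"` (default), `"kmeans"` or `"spectral"`.
#' @param k Number of clusters (k-means / spectral only).
#' @param bandwidth,bandwidth_quantile Mean-shift bandwidth controls.
#' @param prototype `"mean"` (default) or `"median"` aggregation.
#' @param seed RNG seed (k-means restarts, spectral initialization).
#' @return A `cluster_result`: list with `labels`, `algorithm`,
#'   `prototypes`, `silhouette`, `coverage_top5`, `n_clusters`, `space`.
#' @export
cluster_embeddings <- function(emb, days = NULL,
                               algorithm = c("mean_shift", "kmeans", "spectral"),
                               k = NULL, bandwidth = NULL,
                               bandwidth_quantile = 0.2,
                               prototype = c("mean", "median"), seed = 1) {
  algorithm <- match.arg(algorithm)
  prototype <- match.arg(prototype)
  space <- if (inherits(emb, "embedding_set")) emb$vectors else as.matrix(emb)
  if (nrow(space) < 2) stop("need at least 2 days to cluster")
  labels <- run_clustering(space, algorithm, k, bandwidth, bandwidth_quantile,
                           seed)
  met <- cluster_metrics(space, labels)
  protos <- if (!is.null(days)) cluster_prototypes(days, labels, prototype)
  structure(list(labels = labels, algorithm = algorithm, prototypes = protos,
                 silhouette = met$silhouette, coverage_top5 = met$coverage_top5,
                 n_clusters = length(unique(labels)), space = "embedding"),
            class = "cluster_result")
}

#' Cluster raw concatenated daily profiles (baseline)
#'
#' The comparison baseline for [cluster_embeddings()]: each day's sensor
#' profiles are concatenated into one long vector and the same clustering
#' algorithm is applied under the same Euclidean distance, with the
#' silhouette computed in the raw concatenated space.
#'
#' @param days List of daily matrices (bins x sensors).
#' @inheritParams cluster_embeddings
#' @return A `cluster_result` with `space = "raw"`.
#' @export
baseline_raw_clustering <- function(days,
                                    algorithm = c("mean_shift", "kmeans", "spectral"),
                                    k = NULL, bandwidth = NULL,
                                    bandwidth_quantile = 0.2,
                                    prototype = c("mean", "median"), seed = 1) {
  algorithm <- match.arg(algorithm)
  prototype <- match.arg(prototype)
  space <- t(vapply(days, as.numeric, numeric(length(as.numeric(days[[1]])))))
  if (nrow(space) < 2) stop("need at least 2 days to cluster")
  labels <- run_clustering(space, algorithm, k, bandwidth, bandwidth_quantile,
                           seed)
  met <- cluster_metrics(space, labels)
  structure(list(labels = labels, algorithm = algorithm,
                 prototypes = cluster_prototypes(days, labels, prototype),
                 silhouette = met$silhouette, coverage_top5 = met$coverage_top5,
                 n_clusters = length(unique(labels)), space = "raw"),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %s on %s space: %d clusters, silhouette %.3f, top-5 coverage %.1f%%\n",
              x$algorithm, x$space, x$n_clusters, x$silhouette,
              100 * x$coverage_top5))
  invisible(x)
}
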