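#' k-means clustering configuration
#'
#' @param k Number of clusters (`2 <= k <= N`, or `k = N` for the trivial
#'   one-point-per-cluster partition).
#' @param n_init Random restarts; the run with the lowest inertia wins
#'   (default 10).
#' @param max_iter Lloyd iteration cap per restart (default 300).
#' @param seed Integer seed.
#' @param init `"kmeans++"` (default) or `"random"` center seeding.
#' @return A `cluster_config` list.
#' @export
cluster_config <- function(k, n_init = 10L, max_iter = 300L, seed = 1L,
                           init = c("kmeans++", "random")) {
  init <- match.arg(init)
  stopifnot(k >= 1L, n_init >= 1L, max_iter >= 1L)
  structure(list(k = as.integer(k), n_init = as.integer(n_init),
                 max_iter = as.integer(max_iter), seed = as.integer(seed),
                 init = init),
            class = "cluster_config")
}

#' k-means clustering (Lloyd's algorithm)
#'
#' Standard Lloyd iterations — assign each point to its nearest centroid,
#' recompute centroids — run to convergence (assignments unchanged) or
#' `max_iter`, over `n_init` seeded restarts, keeping the restart with the
#' lowest inertia. Centers are seeded with k-means++ by default. A cluster
#' emptied during iteration is re-seeded with the point farthest from its
#' current centroid.
#'
#' @param points Numeric matrix (rows are observations).
#' @param config A [cluster_config()] (or an integer `k`, taken with
#'   default settings).
#' @return A `cluster_result`: list with `labels` (1..k), `centroids`
#'   (`k x dims`), `inertia` (within-cluster sum of squared distances) and
#'   `k`.
#' @export
kmeans_cluster <- function(points, config) {
  if (is.numeric(config) && length(config) == 1L)
    config <- cluster_config(config)
  X <- as.matrix(points)
  n <- nrow(X)
  k <- config$k
  if (k > n) stop("k exceeds the number of points")
  if (n >= 2L && k >= 2L && all(pairwise_sq_distances(X) == 0))
    stop("all points identical: no valid partition into k >= 2 clusters")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  best <- NULL
  for (rep in seq_len(config$n_init)) {
    centers <- if (config$init == "kmeans++") kmeanspp_centers(X, k)
               else X[sample.int(n, k), , drop = FALSE]
    fit <- lloyd(X, centers, config$max_iter)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  structure(list(labels = best$labels, centroids = best$centroids,
                 inertia = best$inertia, k = k, iterations = best$iterations),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: k = %d, inertia %.4g, sizes %s\n",
              x$k, x$inertia, paste(tabulate(x$labels, x$k), collapse = "/")))
  invisible(x)
}

# squared distance of every point to every center
point_center_sq <- function(X, centers) {
  outer(rowSums(X^2), rowSums(centers^2), "+") - 2 * tcrossprod(X, centers)
}

kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- pmax(point_center_sq(X, X[idx[1], , drop = FALSE])[, 1], 0)
    for (j in 2:k) {
      if (sum(d2) == 0) idx[j] <- sample.int(n, 1L)
      else idx[j] <- sample.int(n, 1L, prob = d2)
      d2 <- pmin(d2, pmax(point_center_sq(X, X[idx[j], , drop = FALSE])[, 1], 0))
    }
  }
  X[idx, , drop = FALSE]
}

lloyd <- function(X, centers, max_iter) {
  n <- nrow(X)
  k <- nrow(centers)
  labels <- integer(n)
  for (it in seq_len(max_iter)) {
    d2 <- pmax(point_center_sq(X, centers), 0)
    new_labels <- max.col(-d2, ties.method = "first")
    # repair empty clusters: seed each with the point farthest from its
    # current centroid
    repeat {
      sizes <- tabulate(new_labels, k)
      empty <- which(sizes == 0L)
      if (!length(empty)) break
      far <- which.max(d2[cbind(seq_len(n), new_labels)])
      new_labels[far] <- empty[1]
      d2[far, ] <- 0  # pin: this point defines the re-seeded cluster
    }
    converged <- it > 1L && all(new_labels == labels)
    labels <- new_labels
    for (j in seq_len(k))
      centers[j, ] <- colMeans(X[labels == j, , drop = FALSE])
    if (converged) break
  }
  d2 <- pmax(point_center_sq(X, centers), 0)
  inertia <- sum(d2[cbind(seq_len(n), labels)])
  list(labels = labels, centroids = centers, inertia = inertia, iterations = it)
}

#' Mean silhouette width of a clustering
#'
#' Per point, `s = (b - a) / max(a, b)` where `a` is the mean distance to
#' the other members of its own cluster and `b` the smallest mean distance
#' to the members of any other cluster; singleton-cluster points contribute
#' 0, as does the degenerate 0/0 case. Euclidean distances.
#'
#' @param points Numeric matrix.
#' @param labels Integer cluster labels (>= 2 distinct values).
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
silhouette_mean <- function(points, labels) {
  X <- as.matrix(points)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2L) stop("silhouette needs at least two clusters")
  n <- nrow(X)
  D <- sqrt(pmax(pairwise_sq_distances(X), 0))
  sizes <- tabulate(labels, k)
  # mean distance of each point to each cluster
  md <- sapply(seq_len(k), function(j) rowSums(D[, labels == j, drop = FALSE]))
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- labels[i]
    if (sizes[ci] == 1L) { s[i] <- 0; next }
    a <- md[i, ci] / (sizes[ci] - 1L)
    b <- min(md[i, -ci] / sizes[-ci])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Principal component scores
#'
#' Column-centered projection onto the leading eigenvectors of the
#' covariance matrix (via [stats::prcomp()]); requests beyond the available
#' rank are truncated with a warning.
#'
#' @param X Numeric matrix or `feature_table`.
#' @param n_components Number of components to keep.
#' @return List with `scores` (`N x n_components`), `explained` (variance
#'   fractions, non-increasing) and the `prcomp` fit as `fit`.
#' @export
pca_scores <- function(X, n_components) {
  if (inherits(X, "feature_table") ||
      (is.data.frame(X) && any(c("call_id", "label") %in% names(X))))
    X <- feature_matrix(X)
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite values in input")
  fit <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  avail <- ncol(fit$x)
  if (n_components > avail) {
    warning(sprintf("only %d components available; truncating from %d",
                    avail, n_components))
    n_components <- avail
  }
  vars <- fit$sdev^2
  list(scores = fit$x[, seq_len(n_components), drop = FALSE],
       explained = vars / sum(vars), fit = fit)
}

#' Choose k by average silhouette width
#'
#' Runs k-means for every k in `k_range` and returns the k with the largest
#' mean silhouette width (ties go to the smallest k).
#'
#' @param points Numeric matrix.
#' @param k_range Integer vector of candidate k (within `[2, N - 1]`).
#' @param seed Seed shared by all k-means runs.
#' @param n_init Restarts per k.
#' @return List with `k`, and `silhouette` (named vector over `k_range`).
#' @export
choose_k <- function(points, k_range, seed = 1L, n_init = 10L) {
  if (!length(k_range)) stop("empty k range")
  X <- as.matrix(points)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2L) || any(k_range > nrow(X) - 1L))
    stop("k_range must lie within [2, N - 1]")
  sil <- vapply(k_range, function(k) {
    res <- kmeans_cluster(X, cluster_config(k, seed = seed, n_init = n_init))
    silhouette_mean(X, res$labels)
  }, numeric(1))
  names(sil) <- k_range
  list(k = k_range[which.max(sil)], silhouette = sil)
}

#' Cluster-by-type composition matrix
#'
#' Row r, column t holds the percentage of cluster r's members carrying type
#' label t; every row sums to 100.
#'
#' @param cluster_labels Cluster assignment per call.
#' @param type_labels A-priori vocal-type label per call.
#' @return Matrix (clusters x types) of percentages, class
#'   `composition_matrix`.
#' @export
composition_matrix <- function(cluster_labels, type_labels) {
  stopifnot(length(cluster_labels) == length(type_labels))
  if (!length(cluster_labels)) stop("empty label vectors")
  tab <- table(cluster = cluster_labels, type = type_labels)
  m <- 100 * sweep(unclass(tab), 1, rowSums(tab), "/")
  class(m) <- c("composition_matrix", class(m))
  m
}

#' @export
print.composition_matrix <- function(x, ...) {
  cat("composition matrix (% of cluster members per vocal type):\n")
  print(round(unclass(x), 2), ...)
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b Label vectors of equal length.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
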