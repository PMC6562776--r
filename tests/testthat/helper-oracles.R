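# Brute-force reference implementations used as independent oracles.
# Deliberately naive (double loops, exhaustive enumeration) and kept
# separate from the package's own code paths.

oracle_pairwise_sq <- function(X) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- sum((X[i, ] - X[j, ])^2)
  D
}

oracle_silhouette <- function(X, labels) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(D[i, labels == cl]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

oracle_kappa <- function(cm) {
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- 0
  for (j in seq_len(nrow(cm)))
    pe <- pe + (sum(cm[j, ]) / n) * (sum(cm[, j]) / n)
  (po - pe) / (1 - pe)
}

oracle_mcc <- function(tp, fp, tn, fn) {
  num <- tp * tn - fp * fn
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) 0 else num / den
}

# exhaustive k-means optimum: enumerate every assignment of n points to k
# labels and keep the lowest within-cluster sum of squares over non-empty
# partitions
oracle_kmeans_best <- function(X, k) {
  n <- nrow(X)
  stopifnot(k^n <= 2e6)
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    lab <- as.integer(grid[r, ])
    if (length(unique(lab)) < k) next
    inertia <- 0
    for (j in unique(lab)) {
      pts <- X[lab == j, , drop = FALSE]
      ctr <- colMeans(pts)
      inertia <- inertia + sum(sweep(pts, 2, ctr)^2)
    }
    if (inertia < best) best <- inertia
  }
  best
}

oracle_fd_gradient <- function(P, Y, eps = 1e-6) {
  G <- Y * 0
  for (i in seq_len(nrow(Y))) for (j in seq_len(ncol(Y))) {
    Yp <- Y; Yp[i, j] <- Y[i, j] + eps
    Ym <- Y; Ym[i, j] <- Y[i, j] - eps
    G[i, j] <- (kl_cost(P, low_dim_affinities(Yp)$Q) -
                kl_cost(P, low_dim_affinities(Ym)$Q)) / (2 * eps)
  }
  G
}

# per-class one-vs-rest counts straight from label vectors
oracle_per_class <- function(truth, pred, cls) {
  tp <- sum(truth == cls & pred == cls)
  fp <- sum(truth != cls & pred == cls)
  fn <- sum(truth == cls & pred != cls)
  tn <- sum(truth != cls & pred != cls)
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

make_blobs <- function(n_per, centers, sd = 1, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
      matrix(centers[i, ], n_per, ncol(centers), byrow = TRUE)))
  list(X = X, labels = rep(seq_len(nrow(centers)), each = n_per))
}
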