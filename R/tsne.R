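#' t-SNE configuration
#'
#' Settings for the from-scratch t-distributed stochastic neighbor embedding.
#' The three parameters the repertoire analysis fixes are `perplexity = 40`,
#' `theta = 0.5` and `dims = 2`; the optimizer schedule (learning rate 200,
#' 1000 iterations, early exaggeration 12 for the first 250 iterations,
#' momentum 0.5 switching to 0.8) follows standard t-SNE practice and is
#' fully exposed here.
#'
#' @param perplexity Target effective neighbor count (2^H of each calibrated
#'   conditional distribution). Default 40.
#' @param theta Barnes-Hut accuracy parameter in `[0, 1]`; 0 runs the exact
#'   O(N^2) gradient. Default 0.5.
#' @param dims Output dimensionality (default 2; the Barnes-Hut quadtree
#'   requires 2, other values fall back to the exact gradient).
#' @param n_iter Gradient-descent iterations (default 1000).
#' @param learning_rate Step size (default 200).
#' @param early_exaggeration Affinity multiplier during the opening phase
#'   (default 12, applied for the first 250 iterations, or `n_iter / 2` for
#'   short runs).
#' @param momentum,final_momentum Momentum before/after the switch (defaults
#'   0.5 and 0.8; the switch happens when exaggeration is removed).
#' @param seed Integer seed for the Gaussian initialization.
#' @param calibration_tol Entropy tolerance of the perplexity binary search,
#'   in bits (default 1e-5).
#' @param calibration_max_iter Binary-search iteration cap (default 50).
#' @param input_pca_dims Optional PCA pre-reduction dimensionality applied to
#'   the standardized features (default 50; `NA` disables).
#' @param standardize_input Standardize feature columns to zero mean / unit
#'   variance first (default `TRUE`; duration and band energies live on very
#'   different scales).
#' @return A `tsne_config` list.
#' @export
tsne_config <- function(perplexity = 40, theta = 0.5, dims = 2L,
                        n_iter = 1000L, learning_rate = 200,
                        early_exaggeration = 12, momentum = 0.5,
                        final_momentum = 0.8, seed = 1L,
                        calibration_tol = 1e-5, calibration_max_iter = 50L,
                        input_pca_dims = 50L, standardize_input = TRUE) {
  stopifnot(perplexity > 0, theta >= 0, theta <= 1, dims >= 1L, n_iter >= 1L,
            learning_rate > 0, early_exaggeration >= 1,
            momentum >= 0, momentum < 1, final_momentum >= 0, final_momentum < 1)
  structure(list(perplexity = perplexity, theta = theta, dims = as.integer(dims),
                 n_iter = as.integer(n_iter), learning_rate = learning_rate,
                 early_exaggeration = early_exaggeration, momentum = momentum,
                 final_momentum = final_momentum, seed = as.integer(seed),
                 calibration_tol = calibration_tol,
                 calibration_max_iter = as.integer(calibration_max_iter),
                 input_pca_dims = input_pca_dims,
                 standardize_input = isTRUE(standardize_input)),
            class = "tsne_config")
}

#' Pairwise squared Euclidean distances
#'
#' @param X Numeric matrix, one row per observation.
#' @return Symmetric `N x N` matrix of squared distances, zero diagonal.
#' @export
pairwise_sq_distances <- function(X) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite values in input")
  if (nrow(X) < 2L) stop("need at least two rows")
  sq <- rowSums(X^2)
  D <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  D[D < 0] <- 0
  diag(D) <- 0
  D
}

#' Calibrate one conditional neighbor distribution to a target perplexity
#'
#' Given one point's squared distances to the other points, finds by binary
#' search the Gaussian precision `beta` such that the conditional
#' distribution `p_j ∝ exp(-beta d_j)` has Shannon entropy `H` (bits)
#' matching the target perplexity, `2^H = perplexity`.
#'
#' @param d_row Squared distances to the other points (the point itself
#'   excluded, or flagged via `self`).
#' @param perplexity Target effective neighbor count.
#' @param tol Entropy tolerance in bits.
#' @param max_iter Binary-search cap; if reached the result carries
#'   `converged = FALSE`.
#' @param self Optional index into `d_row` to exclude (forced to zero
#'   probability), when `d_row` includes the point itself.
#' @return List with `beta`, `p` (same length as `d_row`, sums to 1),
#'   `H` (bits) and `converged`.
#' @export
calibrate_row <- function(d_row, perplexity, tol = 1e-5, max_iter = 50L,
                          self = NA_integer_) {
  d <- as.numeric(d_row)
  active <- rep(TRUE, length(d))
  if (!is.na(self)) active[self] <- FALSE
  if (sum(active) < 1L) stop("no neighbors to calibrate against")
  da <- d[active]
  target <- log2(perplexity)
  if (all(da == da[1])) {
    # degenerate: all neighbors equidistant (or all-zero distances); any
    # beta gives the uniform distribution
    if (da[1] == 0)
      warning("all-zero distance row; falling back to uniform conditionals")
    p <- rep(0, length(d))
    p[active] <- 1 / sum(active)
    return(list(beta = 1, p = p,
                H = log2(sum(active)), converged = TRUE))
  }
  beta <- 1
  beta_min <- -Inf
  beta_max <- Inf
  h <- entropy_bits_at(da, beta)
  it <- 0L
  while (abs(h - target) > tol && it < max_iter) {
    if (h > target) {           # too many effective neighbors: sharpen
      beta_min <- beta
      beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2
    } else {
      beta_max <- beta
      beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2
    }
    h <- entropy_bits_at(da, beta)
    it <- it + 1L
  }
  pa <- exp(-beta * (da - min(da)))
  pa <- pa / sum(pa)
  p <- rep(0, length(d))
  p[active] <- pa
  list(beta = beta, p = p, H = h, converged = abs(h - target) <= tol)
}

# Shannon entropy (bits) of p_j ∝ exp(-beta d_j), computed stably
entropy_bits_at <- function(d, beta) {
  e <- exp(-beta * (d - min(d)))
  p <- e / sum(e)
  nz <- p > 0
  -sum(p[nz] * log2(p[nz]))
}

#' Perplexity-calibrated joint affinity matrix
#'
#' Calibrates every row's conditional distribution to the target perplexity
#' and symmetrizes: `p_ij = (p_{j|i} + p_{i|j}) / (2N)`. Duplicate rows are
#' jittered by 1e-10 (with a warning) before distance computation.
#'
#' @param X Numeric matrix of observations (rows).
#' @param config A [tsne_config()] (perplexity, calibration tolerances).
#' @return List with `P` (symmetric, zero diagonal, sums to 1), `betas`, and
#'   mean effective perplexity `mean_perplexity` (mean of per-row 2^H).
#' @export
joint_affinities <- function(X, config = tsne_config()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n <= config$perplexity)
    stop("need N > perplexity observations")
  if (anyDuplicated(X)) {
    warning("duplicate feature rows; adding 1e-10 jitter")
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(config$seed)
    X <- X + matrix(stats::rnorm(length(X), sd = 1e-10), nrow = n)
  }
  D <- pairwise_sq_distances(X)
  P <- matrix(0, n, n)
  betas <- numeric(n)
  hs <- numeric(n)
  for (i in seq_len(n)) {
    cal <- calibrate_row(D[i, ], config$perplexity,
                         tol = config$calibration_tol,
                         max_iter = config$calibration_max_iter, self = i)
    P[i, ] <- cal$p
    betas[i] <- cal$beta
    hs[i] <- cal$H
  }
  P <- (P + t(P)) / (2 * n)
  diag(P) <- 0
  list(P = P, betas = betas, mean_perplexity = mean(2^hs))
}

#' Low-dimensional Student-t affinities
#'
#' Heavy-tailed kernel of the embedding: unnormalized weights
#' `w_ij = (1 + ||y_i - y_j||^2)^-1`, normalized to the joint distribution
#' `Q`.
#'
#' @param Y Numeric `N x dims` coordinate matrix.
#' @return List with `Q` (symmetric, zero diagonal, sums to 1) and the
#'   unnormalized weight matrix `W` (zero diagonal).
#' @export
low_dim_affinities <- function(Y) {
  Y <- as.matrix(Y)
  W <- 1 / (1 + pairwise_sq_distances(Y))
  diag(W) <- 0
  list(Q = W / sum(W), W = W)
}

#' Kullback-Leibler divergence between affinity matrices
#'
#' `sum_ij p_ij log(p_ij / q_ij)` (natural log); zero-probability `p` terms
#' contribute zero.
#'
#' @param P,Q Matched affinity matrices.
#' @return Non-negative scalar.
#' @export
kl_cost <- function(P, Q) {
  stopifnot(all(dim(P) == dim(Q)))
  nz <- P > 0
  sum(P[nz] * log(P[nz] / pmax(Q[nz], 1e-300)))
}

#' Exact t-SNE gradient
#'
#' `dC/dy_i = 4 sum_j (p_ij - q_ij) (1 + ||y_i - y_j||^2)^-1 (y_i - y_j)`.
#'
#' @param P Joint affinity matrix.
#' @param Y Current embedding coordinates.
#' @return `N x dims` gradient matrix (rows sum to zero: the cost is
#'   translation invariant).
#' @export
tsne_gradient <- function(P, Y) {
  Y <- as.matrix(Y)
  ld <- low_dim_affinities(Y)
  M <- (P - ld$Q) * ld$W
  4 * (rowSums(M) * Y - M %*% Y)
}

#' Barnes-Hut t-SNE gradient
#'
#' Approximates the repulsive term of the gradient with a quadtree: any cell
#' whose extent over distance ratio is below `theta` is summarized by its
#' center of mass. The attractive term uses the affinities exactly.
#' `theta = 0` reproduces the exact gradient. Two-dimensional embeddings
#' only.
#'
#' @inheritParams tsne_gradient
#' @param theta Accuracy parameter in `[0, 1]`.
#' @return `N x 2` gradient matrix.
#' @export
tsne_gradient_bh <- function(P, Y, theta = 0.5) {
  Y <- as.matrix(Y)
  if (ncol(Y) != 2L) stop("Barnes-Hut gradient requires a 2-D embedding")
  bh_gradient_cpp(P, Y, theta)
}

#' Run t-SNE on a feature matrix
#'
#' Standardizes and optionally PCA-reduces the input, calibrates the joint
#' affinities to the configured perplexity, initializes the embedding from
#' an isotropic Gaussian (sd 0.01) under the seed, and minimizes the KL
#' divergence by gradient descent with momentum, adaptive per-coordinate
#' gains and early exaggeration. With `theta > 0` (and 2-D output) the
#' gradient uses the Barnes-Hut quadtree approximation; otherwise the exact
#' gradient.
#'
#' @param X Numeric matrix (or `feature_table`) of observations.
#' @param config A [tsne_config()].
#' @return A `tsne_embedding`: list with `Y` (`N x dims`), `final_kl`,
#'   `kl_trace` (cost every 50 iterations, computed exactly),
#'   `mean_perplexity` and `config`.
#' @export
run_tsne <- function(X, config = tsne_config()) {
  if (inherits(X, "feature_table") ||
      (is.data.frame(X) && any(c("call_id", "label") %in% names(X))))
    X <- feature_matrix(X)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4L) stop("too few observations for an embedding")
  if (n < 3 * config$perplexity)
    warning(sprintf("N = %d is small for perplexity %g (N >= 3*perplexity recommended)",
                    n, config$perplexity))
  if (config$standardize_input) {
    mu <- colMeans(X)
    sdv <- apply(X, 2, stats::sd)
    sdv[sdv == 0] <- 1
    X <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  }
  if (!is.na(config$input_pca_dims) && ncol(X) > config$input_pca_dims) {
    k <- min(config$input_pca_dims, n - 1L, ncol(X))
    X <- stats::prcomp(X, center = TRUE, scale. = FALSE)$x[, seq_len(k), drop = FALSE]
  }

  aff <- joint_affinities(X, config)
  P <- aff$P

  use_bh <- config$theta > 0 && config$dims == 2L
  if (config$theta > 0 && config$dims != 2L)
    warning("Barnes-Hut gradient supports dims = 2 only; using the exact gradient")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  Y <- matrix(stats::rnorm(n * config$dims, sd = 1e-2), nrow = n)
  update <- matrix(0, n, config$dims)
  gains <- matrix(1, n, config$dims)
  stop_lying <- min(250L, config$n_iter %/% 2L + 1L)
  P_run <- P * config$early_exaggeration
  mom <- config$momentum
  kl_trace <- c()
  kl_post_exagg <- NA_real_

  for (iter in seq_len(config$n_iter)) {
    if (iter == stop_lying + 1L) {
      P_run <- P
      mom <- config$final_momentum
    }
    G <- if (use_bh) tsne_gradient_bh(P_run, Y, config$theta)
         else tsne_gradient(P_run, Y)
    gains <- ifelse(sign(G) != sign(update), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    update <- mom * update - config$learning_rate * gains * G
    Y <- Y + update
    Y <- sweep(Y, 2, colMeans(Y))
    if (iter == stop_lying + 1L)
      kl_post_exagg <- kl_cost(P, low_dim_affinities(Y)$Q)
    if (iter %% 50L == 0L || iter == config$n_iter)
      kl_trace <- c(kl_trace, kl_cost(P, low_dim_affinities(Y)$Q))
  }
  final_kl <- kl_cost(P, low_dim_affinities(Y)$Q)
  structure(list(Y = Y, final_kl = final_kl, kl_trace = kl_trace,
                 kl_post_exaggeration = kl_post_exagg,
                 mean_perplexity = aff$mean_perplexity, config = config),
            class = "tsne_embedding")
}

#' @export
print.tsne_embedding <- function(x, ...) {
  cat(sprintf("tsne_embedding: %d points in %d-D, final KL %.4f (perplexity %g, theta %g)\n",
              nrow(x$Y), ncol(x$Y), x$final_kl, x$config$perplexity,
              x$config$theta))
  invisible(x)
}
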