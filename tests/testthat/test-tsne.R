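test_that("pairwise squared distances match the brute-force double loop", {
  X <- rbind(c(0, 0), c(3, 4))
  expect_equal(pairwise_sq_distances(X)[1, 2], 25)
  X2 <- rbind(c(1, 2), c(1, 2))
  expect_true(all(pairwise_sq_distances(X2) == 0))
  set.seed(5)
  X3 <- matrix(rnorm(50), 10)
  expect_equal(pairwise_sq_distances(X3), oracle_pairwise_sq(X3), tolerance = 1e-12)
  expect_error(pairwise_sq_distances(matrix(c(1, NA), 2)), "finite")
})

test_that("perplexity calibration matches targets, symmetry and a grid search", {
  # equidistant neighbors are uniform for any precision
  cal <- calibrate_row(c(2, 2, 2), perplexity = 2)
  expect_equal(cal$p, rep(1 / 3, 3))

  # binary-search beta agrees with a fine grid search
  set.seed(11)
  d <- as.numeric(pairwise_sq_distances(matrix(rnorm(50 * 5), 50))[1, -1])
  cal2 <- calibrate_row(d, perplexity = 10)
  grid <- exp(seq(log(1e-4), log(1e4), length.out = 20000))
  ent <- vapply(grid, function(b) {
    e <- exp(-b * (d - min(d))); p <- e / sum(e); -sum(p[p > 0] * log2(p[p > 0]))
  }, numeric(1))
  beta_grid <- grid[which.min(abs(ent - log2(10)))]
  expect_equal(cal2$beta, beta_grid, tolerance = 1e-3)
  expect_equal(sum(cal2$p), 1, tolerance = 1e-12)
  expect_equal(2^cal2$H, 10, tolerance = 1e-4)

  # mean effective perplexity across a random table hits the target
  set.seed(12)
  aff <- joint_affinities(matrix(rnorm(100 * 20), 100), tsne_config(perplexity = 15))
  expect_equal(aff$mean_perplexity, 15, tolerance = 0.15)

  # all-zero distances fall back to uniform with a warning
  expect_warning(cal3 <- calibrate_row(c(0, 0, 0, 0), perplexity = 2), "uniform")
  expect_equal(cal3$p, rep(0.25, 4))
})

test_that("joint affinities are symmetric, unit-sum, zero-diagonal", {
  set.seed(13)
  X <- matrix(rnorm(40 * 6), 40)
  P <- joint_affinities(X, tsne_config(perplexity = 8))$P
  expect_equal(sum(P), 1, tolerance = 1e-9)
  expect_equal(P, t(P), tolerance = 1e-15)
  expect_true(all(diag(P) == 0))
  expect_true(all(P >= 0))

  # three mutually equidistant points: all off-diagonal entries equal
  tri <- diag(3)  # pairwise squared distance exactly 2
  P3 <- joint_affinities(tri, tsne_config(perplexity = 2))$P
  off <- P3[upper.tri(P3)]
  expect_equal(max(off) - min(off), 0, tolerance = 1e-12)

  # two near-identical points among scattered others are mutual favorites
  set.seed(14)
  X4 <- rbind(matrix(rnorm(20 * 3, sd = 5), 20), c(0, 0, 0), c(1e-4, 0, 0))
  P4 <- joint_affinities(X4, tsne_config(perplexity = 5))$P
  expect_equal(which.max(P4[21, ]), 22L)
  expect_equal(which.max(P4[22, ]), 21L)

  # exactly duplicated rows get jitter, with a warning
  expect_warning(joint_affinities(X4[c(1:10, 1), ], tsne_config(perplexity = 3)),
                 "jitter")

  expect_error(joint_affinities(matrix(rnorm(10), 5), tsne_config(perplexity = 10)),
               "perplexity")
})

test_that("the Student-t kernel matches hand computation and is monotone", {
  Y <- rbind(c(0, 0), c(1, 0), c(0, 2), c(3, 3))
  ld <- low_dim_affinities(Y)
  W_hand <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) if (i != j)
    W_hand[i, j] <- 1 / (1 + sum((Y[i, ] - Y[j, ])^2))
  expect_equal(ld$W, W_hand, tolerance = 1e-12)
  expect_equal(sum(ld$Q), 1, tolerance = 1e-12)

  same <- matrix(1, 5, 2)
  Qs <- low_dim_affinities(same)$Q
  expect_equal(max(Qs[upper.tri(Qs)]) - min(Qs[upper.tri(Qs)]), 0)

  Wbig <- low_dim_affinities(10 * Y)$W
  expect_true(all(Wbig[upper.tri(Wbig)] < ld$W[upper.tri(ld$W)]))
})

test_that("KL cost has its closed-form values and brute-force equality", {
  set.seed(15)
  Y <- matrix(rnorm(12), 6)
  Q <- low_dim_affinities(Y)$Q
  expect_equal(kl_cost(Q, Q), 0, tolerance = 1e-12)

  P2 <- matrix(c(0, 0.5, 0.5, 0), 2)
  Q2 <- matrix(c(0, 0.9, 0.1, 0), 2)
  # symmetric matrices built from the two-pair toy: p log p/q summed
  expect_equal(kl_cost(P2 / sum(P2), Q2 / sum(Q2)),
               0.5 * log(0.5 / 0.9) + 0.5 * log(0.5 / 0.1),
               tolerance = 1e-12)

  P <- matrix(runif(36), 6); P <- P + t(P); diag(P) <- 0; P <- P / sum(P)
  acc <- 0
  for (i in 1:6) for (j in 1:6) if (P[i, j] > 0)
    acc <- acc + P[i, j] * log(P[i, j] / Q[i, j])
  expect_equal(kl_cost(P, Q), acc, tolerance = 1e-12)
})

test_that("the exact gradient matches finite differences and is translation invariant", {
  set.seed(16)
  for (rep in 1:5) {
    X <- matrix(rnorm(10 * 4), 10)
    P <- joint_affinities(X, tsne_config(perplexity = 3))$P
    Y <- matrix(rnorm(20, sd = 0.5), 10)
    G <- tsne_gradient(P, Y)
    expect_equal(G, oracle_fd_gradient(P, Y), tolerance = 1e-4)
    expect_equal(colSums(G), c(0, 0), tolerance = 1e-10)
    expect_equal(tsne_gradient(P, sweep(Y, 2, c(5, -3), "+")), G, tolerance = 1e-9)
  }
})

test_that("Barnes-Hut gradients agree with the exact gradient", {
  set.seed(17)
  X <- matrix(rnorm(150 * 5), 150)
  P <- joint_affinities(X, tsne_config(perplexity = 20))$P
  Y <- matrix(rnorm(300), 150)
  G <- tsne_gradient(P, Y)
  expect_equal(tsne_gradient_bh(P, Y, theta = 0), G, tolerance = 1e-10)
  Gbh <- tsne_gradient_bh(P, Y, theta = 0.5)
  expect_lt(max(abs(Gbh - G)) / max(abs(G)), 1e-2)
  expect_error(tsne_gradient_bh(P, matrix(rnorm(450), 150), 0.5), "2-D")
})

test_that("t-SNE separates well-separated Gaussian blobs and is seeded-deterministic", {
  # between-center distance 40 at unit component sd, i.e. more than twice
  # the ~17.4 within-blob rms diameter in 151-D, so the blobs are disjoint
  centers <- matrix(0, 2, 151)
  centers[2, ] <- 40 / sqrt(151)
  blobs <- make_blobs(50, centers, sd = 1, seed = 18)
  cfg <- tsne_config(perplexity = 15, seed = 42)
  emb <- run_tsne(blobs$X, cfg)
  expect_gt(silhouette_mean(emb$Y, blobs$labels), 0.8)
  expect_lte(emb$final_kl, emb$kl_post_exaggeration)
  emb2 <- run_tsne(blobs$X, cfg)
  expect_identical(emb$Y, emb2$Y)
  # exact arm behaves the same way
  emb0 <- run_tsne(blobs$X, tsne_config(perplexity = 15, seed = 42, theta = 0))
  expect_gt(silhouette_mean(emb0$Y, blobs$labels), 0.8)
})

test_that("the embedding preserves neighborhoods far better than chance", {
  centers <- diag(4)[, rep(1:4, length.out = 30)] * 12
  centers <- matrix(rnorm(4 * 30, sd = 0.1), 4) + centers  # 4 distinct centers in 30-D
  blobs <- make_blobs(25, centers, sd = 1, seed = 19)
  emb <- run_tsne(blobs$X, tsne_config(perplexity = 10, n_iter = 500, seed = 7))
  knn_agreement <- function(Y, labels, k = 10) {
    D <- as.matrix(dist(Y))
    diag(D) <- Inf
    mean(vapply(seq_len(nrow(Y)), function(i) {
      nn <- order(D[i, ])[seq_len(k)]
      mean(labels[nn] == labels[i])
    }, numeric(1)))
  }
  set.seed(20)
  random_Y <- matrix(rnorm(nrow(blobs$X) * 2), ncol = 2)
  expect_gte(knn_agreement(emb$Y, blobs$labels),
             3 * knn_agreement(random_Y, blobs$labels))
})
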