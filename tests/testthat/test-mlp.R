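test_that("stratified splits hit the global and per-class targets reproducibly", {
  labels <- rep(c("a", "b"), each = 50)
  sp <- stratified_split(labels, 0.67, seed = 1)
  expect_length(sp$train, 67L)
  expect_length(sp$test, 33L)
  expect_setequal(c(sp$train, sp$test), 1:100)
  tr <- table(labels[sp$train])
  expect_true(all(abs(tr - 33.5) <= 1))
  expect_identical(stratified_split(labels, 0.67, seed = 1), sp)
  expect_false(identical(stratified_split(labels, 0.67, seed = 2)$train, sp$train))

  set.seed(30)
  for (rep in 1:5) {
    labs <- sample(letters[1:4], 80, TRUE, prob = c(0.5, 0.3, 0.15, 0.05))
    if (any(table(labs) < 2)) next
    s <- stratified_split(labs, 0.67, seed = rep)
    expect_length(s$train, round(0.67 * 80))
    got <- table(factor(labs[s$train], levels = letters[1:4]))
    ideal <- 0.67 * table(factor(labs, levels = letters[1:4]))
    expect_true(all(abs(got - ideal) <= 1.5))
  }
  expect_error(stratified_split(c("a", "a", "b"), 0.67), "at least 2")
})

test_that("the perceptron learns XOR and separable blobs deterministically", {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y <- c("lo", "hi", "hi", "lo")
  cfg <- mlp_config(learning_rate = 0.5, momentum = 0.2, epochs = 3000,
                    hidden_units = 4, seed = 3)
  model <- train_mlp(X, y, cfg)
  expect_equal(predict_class(model, X), y)

  blobs <- make_blobs(100, rbind(c(0, 0), c(6, 6)), sd = 1, seed = 31)
  labs <- c("a", "b")[blobs$labels]
  m2 <- train_mlp(blobs$X, labs, mlp_config(seed = 4))
  expect_gte(mean(predict_class(m2, blobs$X) == labs), 0.99)
  # overfit separable model is confident on its training points
  expect_gte(min(predict_proba(m2, blobs$X)[cbind(1:200, match(labs, m2$classes))]),
             0.9)

  m3 <- train_mlp(blobs$X, labs, mlp_config(seed = 4))
  expect_identical(m2$W1, m3$W1)
  expect_identical(m2$W2, m3$W2)
  expect_error(train_mlp(blobs$X, rep("a", 200)), "single class")
})

test_that("the perceptron and a reference net both master a separable problem", {
  blobs <- make_blobs(60, rbind(c(0, 0), c(5, 0), c(2.5, 4)), sd = 0.8, seed = 32)
  labs <- letters[blobs$labels]
  sp <- stratified_split(labs, 0.67, seed = 5)
  ours <- train_mlp(blobs$X[sp$train, ], labs[sp$train],
                    mlp_config(epochs = 200, seed = 5))
  acc_ours <- mean(predict_class(ours, blobs$X[sp$test, ]) == labs[sp$test])
  ref <- nnet::nnet(blobs$X[sp$train, ], nnet::class.ind(labs[sp$train]),
                    size = 5, maxit = 200, trace = FALSE)
  acc_ref <- mean(letters[max.col(predict(ref, blobs$X[sp$test, ]))] == labs[sp$test])
  expect_gte(acc_ours, 0.95)
  expect_gte(acc_ref, 0.95)
})

test_that("class scores are normalized, order-equivariant and shape-checked", {
  blobs <- make_blobs(30, rbind(c(0, 0), c(4, 4)), sd = 1, seed = 33)
  labs <- c("a", "b")[blobs$labels]
  model <- train_mlp(blobs$X, labs, mlp_config(epochs = 50, seed = 6))
  P <- predict_proba(model, blobs$X)
  expect_equal(rowSums(P), rep(1, 60), tolerance = 1e-9)
  expect_true(all(P >= 0))
  perm <- sample(60)
  expect_equal(predict_proba(model, blobs$X[perm, ]), P[perm, ])
  expect_error(predict_proba(model, blobs$X[, 1, drop = FALSE]), "feature count")
})

test_that("evaluation reproduces the printed overall accuracy from its counts", {
  # 1059 of 1109 test instances correct
  k <- 8
  truth <- rep(letters[1:k], length.out = 1109)
  pred <- truth
  wrong <- seq_len(50)
  pred[wrong] <- letters[(match(truth[wrong], letters) %% k) + 1]
  proba <- matrix(0.001, 1109, k, dimnames = list(NULL, letters[1:k]))
  proba[cbind(seq_len(1109), match(pred, letters[1:k]))] <- 1
  proba <- proba / rowSums(proba)
  rep_ <- evaluate(truth, proba)
  expect_equal(sum(diag(rep_$confusion_counts)), 1059)
  expect_equal(rep_$n, 1109)
  expect_equal(round(rep_$accuracy, 2), 95.49)
})

test_that("perfect predictions give the ceiling values of every statistic", {
  truth <- rep(c("a", "b", "c"), times = c(5, 3, 2))
  proba <- matrix(0, 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  proba[cbind(1:10, match(truth, c("a", "b", "c")))] <- 1
  r <- evaluate(truth, proba)
  expect_equal(r$accuracy, 100)
  expect_equal(r$kappa, 1)
  expect_equal(r$mae, 0)
  expect_equal(r$rmse, 0)
  expect_true(all(r$per_class$tp_rate == 1))
  expect_true(all(r$per_class$fp_rate == 0))
  expect_true(all(r$per_class$precision == 1))
  expect_equal(r$per_class$mcc, rep(1, 3))
  expect_true(all(r$per_class$roc_area == 1))
})

test_that("kappa, MCC and per-class rates match formula oracles on random data", {
  cm <- matrix(c(40, 10, 20, 30), 2, byrow = TRUE)
  expect_equal(cohen_kappa(cm), 0.4, tolerance = 1e-12)

  set.seed(34)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    cmr <- matrix(rpois(k * k, 8), k)
    expect_equal(cohen_kappa(cmr), oracle_kappa(cmr), tolerance = 1e-12)
  }

  # a full evaluation against direct counting
  set.seed(35)
  k <- 4
  cls <- letters[1:k]
  truth <- sample(cls, 150, TRUE)
  pred <- ifelse(runif(150) < 0.7, truth, sample(cls, 150, TRUE))
  proba <- matrix(runif(150 * k, 0, 0.2), 150, k, dimnames = list(NULL, cls))
  proba[cbind(1:150, match(pred, cls))] <- 1
  proba <- proba / rowSums(proba)
  r <- evaluate(truth, proba)
  expect_equal(class_order <- r$per_class$class, cls)
  for (j in seq_len(k)) {
    cnt <- oracle_per_class(truth, pred, cls[j])
    expect_equal(r$per_class$tp_rate[j], cnt$tp / (cnt$tp + cnt$fn))
    expect_equal(r$per_class$fp_rate[j], cnt$fp / (cnt$fp + cnt$tn))
    expect_equal(r$per_class$precision[j],
                 if (cnt$tp + cnt$fp == 0) 0 else cnt$tp / (cnt$tp + cnt$fp))
    expect_equal(r$per_class$f_measure[j],
                 2 * cnt$tp / (2 * cnt$tp + cnt$fp + cnt$fn))
    expect_equal(r$per_class$mcc[j], oracle_mcc(cnt$tp, cnt$fp, cnt$tn, cnt$fn),
                 tolerance = 1e-12)
  }
  # MAE/RMSE against direct expressions
  onehot <- matrix(0, 150, k)
  onehot[cbind(1:150, match(truth, cls))] <- 1
  expect_equal(r$mae, mean(abs(proba - onehot)), tolerance = 1e-12)
  expect_equal(r$rmse, sqrt(mean((proba - onehot)^2)), tolerance = 1e-12)
})

test_that("accuracy and kappa are invariant to class-order permutation", {
  set.seed(36)
  cls <- c("a", "b", "c")
  truth <- sample(cls, 90, TRUE)
  proba <- matrix(runif(270), 90, 3, dimnames = list(NULL, cls))
  proba <- proba / rowSums(proba)
  r1 <- evaluate(truth, proba)
  perm <- c("c", "a", "b")
  r2 <- evaluate(truth, proba[, perm], class_order = perm)
  expect_equal(r2$accuracy, r1$accuracy)
  expect_equal(r2$kappa, r1$kappa)
  expect_equal(r2$mae, r1$mae)
})

test_that("ROC and PRC areas behave at their reference points", {
  set.seed(37)
  pos <- rep(c(TRUE, FALSE), each = 1000)
  auc_rand <- roc_auc(pos, runif(2000))
  expect_lt(abs(auc_rand - 0.5), 0.05)
  # perfect separation
  expect_equal(roc_auc(pos, ifelse(pos, 1, 0)), 1)
  expect_equal(prc_auc(pos, ifelse(pos, 1, 0)), 1)
  # reference implementation agreement
  for (rep in 1:5) {
    p <- sample(c(TRUE, FALSE), 100, TRUE)
    s <- round(runif(100), 2)  # deliberate score ties
    ref <- as.numeric(pROC::auc(pROC::roc(p, s, quiet = TRUE, direction = "<")))
    expect_equal(roc_auc(p, s), ref, tolerance = 1e-9)
  }
})

test_that("percentage confusion matrices are column-stochastic per true class", {
  cmd <- diag(c(5L, 8L, 2L))
  pct <- confusion_percent(cmd)
  expect_equal(diag(pct), rep(100, 3))

  cm2 <- matrix(c(99, 1, 0, 10), 2, byrow = TRUE)
  pct2 <- confusion_percent(cm2)
  expect_equal(pct2[, 1], c(99, 1), ignore_attr = TRUE)

  set.seed(38)
  for (rep in 1:10) {
    k <- sample(2:6, 1)
    cmr <- matrix(rpois(k * k, 5), k) + diag(k)  # ensure support
    expect_true(all(abs(colSums(confusion_percent(cmr)) - 100) < 0.05))
  }
  expect_warning(confusion_percent(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
                 "zero-support")
})
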