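#' Multilayer-perceptron configuration
#'
#' A single-hidden-layer perceptron trained by online (per-instance)
#' backpropagation of squared error with a momentum term, the classifier the
#' repertoire analysis uses for call recognition: sigmoid hidden and output
#' units, one-hot targets, learning rate 0.2, momentum 0.2, 500 epochs, and
#' a 67% training split. The default hidden-layer size is
#' `ceiling((n_features + n_classes) / 2)` (the common 'a' sizing rule).
#'
#' @param learning_rate Step size (> 0, default 0.2).
#' @param momentum Momentum coefficient in `[0, 1)` (default 0.2).
#' @param epochs Training passes over the data (default 500).
#' @param hidden_units Hidden-layer size; `NA` (default) applies the sizing
#'   rule at fit time.
#' @param train_fraction Fraction of instances used for training (default
#'   0.67).
#' @param seed Integer seed (weight initialization and epoch shuffling).
#' @return An `mlp_config` list.
#' @export
mlp_config <- function(learning_rate = 0.2, momentum = 0.2, epochs = 500L,
                       hidden_units = NA_integer_, train_fraction = 0.67,
                       seed = 1L) {
  stopifnot(learning_rate > 0, momentum >= 0, momentum < 1, epochs >= 1L,
            train_fraction > 0, train_fraction < 1)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs),
                 hidden_units = as.integer(hidden_units),
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "mlp_config")
}

#' Stratified train/test split
#'
#' Per-class training counts are `round(fraction * n_class)`, then adjusted
#' (on the classes with the largest rounding remainders) so the total equals
#' `round(fraction * N)` exactly, with at least one training and one test
#' instance per class. The split is disjoint, exhaustive and reproducible
#' under the seed.
#'
#' @param labels Class label per instance.
#' @param train_fraction Fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_fraction = 0.67, seed = 1L) {
  labels <- as.character(labels)
  n <- length(labels)
  counts <- table(labels)
  if (any(counts < 2L))
    stop("every class needs at least 2 instances to split: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  target_total <- round(train_fraction * n)
  raw <- train_fraction * as.numeric(counts)
  take <- round(raw)
  take <- pmin(pmax(take, 1L), as.numeric(counts) - 1L)
  diff <- target_total - sum(take)
  if (diff != 0) {
    rem <- raw - floor(raw)
    ord <- order(if (diff > 0) -rem else rem)
    for (j in ord) {
      if (diff == 0) break
      step <- sign(diff)
      cand <- take[j] + step
      if (cand >= 1L && cand <= counts[j] - 1L) {
        take[j] <- cand
        diff <- diff - step
      }
    }
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  train <- integer(0)
  for (j in seq_along(counts)) {
    idx <- which(labels == names(counts)[j])
    train <- c(train, sample(idx, take[j]))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Train the multilayer perceptron
#'
#' Inputs are standardized with training-set statistics (stored in the
#' model). Weights start uniform in `[-0.5, 0.5]` under the seed; each epoch
#' visits the training instances in a fresh shuffled order and applies, per
#' instance, the momentum update
#' `delta_w <- -lr * grad + momentum * delta_w_prev`.
#'
#' @param X Numeric feature matrix (training rows).
#' @param labels Class label per row (>= 2 distinct classes).
#' @param config An [mlp_config()].
#' @return An `mlp_model`: weights `W1` (hidden x (features+1)) and `W2`
#'   (classes x (hidden+1)), `classes` (label ordering fixed at fit time),
#'   standardization parameters, and the config.
#' @export
train_mlp <- function(X, labels, config = mlp_config()) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite features")
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("training set has a single class")
  n <- nrow(X)
  d <- ncol(X)
  c_out <- length(classes)
  h <- config$hidden_units
  if (is.na(h)) h <- as.integer(ceiling((d + c_out) / 2))

  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")

  Tgt <- matrix(0, n, c_out)
  Tgt[cbind(seq_len(n), match(labels, classes))] <- 1

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  W1 <- matrix(stats::runif(h * (d + 1L), -0.5, 0.5), nrow = h)
  W2 <- matrix(stats::runif(c_out * (h + 1L), -0.5, 0.5), nrow = c_out)
  dW1 <- matrix(0, h, d + 1L)
  dW2 <- matrix(0, c_out, h + 1L)
  lr <- config$learning_rate
  mom <- config$momentum

  for (ep in seq_len(config$epochs)) {
    for (i in sample.int(n)) {
      x1 <- c(Xs[i, ], 1)
      a1 <- c(sigmoid(W1 %*% x1), 1)
      o <- sigmoid(W2 %*% a1)
      # squared-error output delta for sigmoid units
      d2 <- (o - Tgt[i, ]) * o * (1 - o)
      hid <- a1[seq_len(h)]
      d1 <- (crossprod(W2[, seq_len(h), drop = FALSE], d2)) * hid * (1 - hid)
      dW2 <- -lr * tcrossprod(d2, a1) + mom * dW2
      dW1 <- -lr * tcrossprod(d1, x1) + mom * dW1
      W2 <- W2 + dW2
      W1 <- W1 + dW1
    }
  }
  structure(list(W1 = W1, W2 = W2, classes = classes, mu = mu, sd = sdv,
                 config = config),
            class = "mlp_model")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("mlp_model: %d -> %d -> %d (classes: %s)\n",
              ncol(x$W1) - 1L, nrow(x$W1), nrow(x$W2),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Class-membership scores of a fitted perceptron
#'
#' Sigmoid outputs normalized to sum to one per instance; the predicted
#' class is the per-row argmax.
#'
#' @param model An `mlp_model`.
#' @param X Feature matrix with the same columns the model was trained on.
#' @return Matrix (`nrow(X)` x classes) of non-negative scores with unit row
#'   sums; column names are the class labels.
#' @export
predict_proba <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$W1) - 1L)
    stop(sprintf("feature count %d does not match model (%d)",
                 ncol(X), ncol(model$W1) - 1L))
  Xs <- sweep(sweep(X, 2, model$mu), 2, model$sd, "/")
  H <- sigmoid(cbind(Xs, 1) %*% t(model$W1))
  O <- sigmoid(cbind(H, 1) %*% t(model$W2))
  P <- O / rowSums(O)
  colnames(P) <- model$classes
  P
}

#' Predicted class labels
#' @inheritParams predict_proba
#' @return Character vector of predicted class labels.
#' @export
predict_class <- function(model, X) {
  P <- predict_proba(model, X)
  model$classes[max.col(P, ties.method = "first")]
}
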