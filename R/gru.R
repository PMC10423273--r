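#' Fit a gated recurrent unit (GRU) network on kinematic chunks
#'
#' The decoding engine: a single recurrent hidden layer of GRU cells reads a
#' `T x K` chunk of kinematics one time step at a time; the final hidden
#' state feeds a dense output layer — softmax over classes for
#' classification, linear with one unit per output for regression. Training
#' minimizes categorical cross-entropy (classification) or mean squared
#' error (regression) with the Adam optimizer (learning rate 0.001, batch
#' size 32 by default), via full backpropagation through time, and is early
#' stopped when the loss on a held-out validation split (20% of the training
#' set by default, stratified by class for classifiers) has not improved for
#' `patience` epochs; the best-validation weights are restored.
#'
#' Per-feature z-scoring is fitted on the training data (default on) and
#' reapplied at prediction time. All randomness (weight initialization,
#' validation split, batch shuffling) flows through R's RNG, so results are
#' reproducible under [set.seed()].
#'
#' @param x Numeric array `n x T x K` of input chunks.
#' @param y Class labels (factor/character, classification) or a numeric
#'   matrix `n x C` of targets (regression).
#' @param type `"classification"` or `"regression"` (inferred from `y` by
#'   default).
#' @param units Number of GRU units (default 100).
#' @param learning_rate,batch_size Adam settings.
#' @param epochs Maximum training epochs (desk-scale default 500; raise
#'   toward 10000 with `patience = 500` for full-scale runs).
#' @param patience Early-stopping patience in epochs.
#' @param validation_split Fraction of the training set held out to monitor
#'   early stopping (0 disables; training loss is then monitored).
#' @param standardize Fit per-feature z-scoring on the training chunks.
#' @param seed Optional integer; if given, `set.seed(seed)` is called first.
#' @return An object of class `gru_fit` with elements `weights`, `history`
#'   (train/validation loss per epoch), `best_epoch`, `levels` (classifier
#'   class labels), scaling parameters and the call settings.
#' @examples
#' set.seed(1)
#' x <- array(rnorm(40 * 8 * 6), c(40, 8, 6))
#' x[1:20, , 1] <- x[1:20, , 1] + 4
#' fit <- gru_fit(x, rep(c("a", "b"), each = 20), units = 8, epochs = 300,
#'                patience = 100)
#' mean(predict(fit, x, type = "class") == rep(c("a", "b"), each = 20))
#' @export
gru_fit <- function(x, y, type = NULL, units = 100, learning_rate = 0.001,
                    batch_size = 32, epochs = 500, patience = 50,
                    validation_split = 0.2, standardize = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(dim(x)) != 3) stop("'x' must be an n x T x K array")
  n <- dim(x)[1]
  if (is.null(type))
    type <- if (is.numeric(y)) "regression" else "classification"
  type <- match.arg(type, c("classification", "regression"))

  if (type == "classification") {
    y <- as.factor(y)
    if (nlevels(droplevels(y)) < 2)
      stop("classification needs at least 2 classes present in 'y'")
    levels_y <- levels(droplevels(y))
    y <- droplevels(y)
    Y <- diag(length(levels_y))[as.integer(y), , drop = FALSE]
  } else {
    Y <- as.matrix(y)
    levels_y <- NULL
  }
  if (nrow(Y) != n) stop("'y' length does not match 'x'")

  center <- rep(0, dim(x)[3]); scale <- rep(1, dim(x)[3])
  if (standardize) {
    for (k in seq_len(dim(x)[3])) {
      center[k] <- mean(x[, , k])
      s <- stats::sd(as.numeric(x[, , k]))
      scale[k] <- if (is.finite(s) && s > 0) s else 1
      x[, , k] <- (x[, , k] - center[k]) / scale[k]
    }
  }

  val_idx <- integer(0)
  if (validation_split > 0 && n >= 10) {
    if (type == "classification") {
      for (cl in levels_y) {
        idx <- which(y == cl)
        n_val <- max(1L, round(validation_split * length(idx)))
        val_idx <- c(val_idx, sample(idx, n_val))
      }
    } else {
      val_idx <- sample.int(n, max(1L, round(validation_split * n)))
    }
  }
  tr_idx <- setdiff(seq_len(n), val_idx)

  fit <- cpp_gru_train(x[tr_idx, , , drop = FALSE],
                       Y[tr_idx, , drop = FALSE],
                       if (length(val_idx))
                         x[val_idx, , , drop = FALSE] else numeric(0),
                       if (length(val_idx))
                         Y[val_idx, , drop = FALSE] else matrix(0, 0, ncol(Y)),
                       type == "classification", as.integer(units),
                       learning_rate, as.integer(batch_size),
                       as.integer(epochs), as.integer(patience))

  structure(list(weights = fit$weights,
                 history = list(train_loss = fit$train_loss,
                                val_loss = fit$val_loss),
                 best_epoch = fit$best_epoch,
                 best_loss = fit$best_loss,
                 type = type,
                 levels = levels_y,
                 center = center, scale = scale,
                 units = units,
                 chunk_dim = dim(x)[2:3]),
            class = "gru_fit")
}

#' Predict from a fitted GRU network
#'
#' @param object A [gru_fit()] result.
#' @param x Array `n x T x K` of chunks (same T, K as in training).
#' @param type `"prob"` (class probabilities), `"class"` (labels) or
#'   `"response"` (regression outputs; the only choice for regressors).
#' @param ... Unused.
#' @return Matrix of probabilities/outputs, or a character vector of labels.
#' @export
predict.gru_fit <- function(object, x, type = c("prob", "class", "response"),
                            ...) {
  type <- match.arg(type)
  if (length(dim(x)) != 3) stop("'x' must be an n x T x K array")
  if (!all(dim(x)[2:3] == object$chunk_dim))
    stop("chunk dimensions do not match the fitted model")
  for (k in seq_len(dim(x)[3]))
    x[, , k] <- (x[, , k] - object$center[k]) / object$scale[k]
  out <- cpp_gru_predict(x, object$weights,
                         object$type == "classification")
  if (object$type == "classification") {
    colnames(out) <- object$levels
    if (type == "class") return(object$levels[max.col(out, ties.method = "first")])
    return(out)
  }
  out
}

#' @export
print.gru_fit <- function(x, ...) {
  cat(sprintf("GRU %s: %d units, chunks %d x %d",
              x$type, x$units, x$chunk_dim[1], x$chunk_dim[2]))
  if (x$type == "classification")
    cat(sprintf(", %d classes", length(x$levels)))
  cat(sprintf("\n  trained %d epochs (best %d), monitored loss %.4g\n",
              length(x$history$train_loss), x$best_epoch, x$best_loss))
  invisible(x)
}
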