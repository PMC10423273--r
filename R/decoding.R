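#' Time-resolved accuracy of a goal classifier on test trials
#'
#' Evaluates a trained classifier on a chunked test dataset (built with an
#' inference stride, typically 1): for every chunk end position, the accuracy
#' is the fraction of test trials whose chunk ending there is classified as
#' the trial's final endpoint.
#'
#' @param model A [gru_fit()] classifier, or (mainly for testing) a function
#'   taking the chunk array and returning predicted class labels.
#' @param dataset A dataset from [build_goal_dataset()].
#' @return A data frame with `end_index` and `accuracy`.
#' @export
evaluate_accuracy_curve <- function(model, dataset) {
  pred <- if (is.function(model)) model(dataset$x)
          else predict(model, dataset$x, type = "class")
  correct <- pred == as.character(dataset$y)
  acc <- tapply(correct, dataset$end_index, mean)
  data.frame(end_index = as.integer(names(acc)),
             accuracy = as.numeric(acc))
}

#' Cross-validated sliding-window decoding of reaching goals
#'
#' The central analysis: can the final reaching target be read out from past
#' kinematics, and from when during the movement? Trials of a
#' [decoding_problem()] are split into stratified folds at the trial level
#' (all chunks of a trial stay on one side, so no chunk-level leakage). In
#' each fold a GRU classifier is trained on chunks slid with `train_stride`
#' (4 by default) over the 100-sample normalized trials, and evaluated on the
#' held-out trials with unit stride, yielding a 93-node accuracy curve
#' indexed by the chunk's last sample; curves are averaged across folds.
#'
#' @param session A `reach_session`.
#' @param dimension,problem Passed to [decoding_problem()].
#' @param window `"movement"` (normalized movement) or `"pre_movement"` (the
#'   raw 500 ms before onset).
#' @param folds Number of stratified cross-validation folds (default 5).
#' @param chunk_len,train_stride Chunking of the training set (T = 8,
#'   stride 4 by default); inference always uses stride 1.
#' @param mode `"pooled"` (default: one network per fold, trained on chunks
#'   from all window positions) or `"per_window"` (a separate network per
#'   training window position, evaluated at those positions only).
#' @param permute_labels If `TRUE`, the final-endpoint labels of the
#'   *training* trials are randomly permuted within each fold while the test
#'   labels stay intact — the standard permutation null for decoding
#'   accuracy, whose expectation is exactly the chance level. (Permuting all
#'   labels before the fold split would not be a null: a classifier can then
#'   recover the plurality permuted label of each kinematic cluster and score
#'   above 1/n_classes.)
#' @param units,epochs,patience,learning_rate,batch_size,validation_split
#'   Passed to [gru_fit()].
#' @param seed Optional integer seed (fold assignment, permutation, network
#'   initialization and shuffling all derive from it).
#' @return An object of class `goal_decoding`: `curve` (fold-averaged
#'   data frame with `end_index`, `pct_movement`, `accuracy`), `fold_curves`
#'   (folds x nodes matrix), `chance`, `classes`, `fold` (per-trial fold
#'   ids), plus the problem description and settings.
#' @export
decode_goals <- function(session,
                         dimension = c("horizontal", "sagittal"),
                         problem = "static",
                         window = c("movement", "pre_movement"),
                         folds = 5, chunk_len = 8, train_stride = 4,
                         mode = c("pooled", "per_window"),
                         permute_labels = FALSE,
                         units = 100, epochs = 500, patience = 50,
                         learning_rate = 0.001, batch_size = 32,
                         validation_split = 0.2, seed = NULL) {
  dimension <- match.arg(dimension)
  window <- match.arg(window)
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)

  prob <- decoding_problem(session, dimension, problem)
  y_trial <- factor(vapply(prob$trials, `[[`, "", "final_id"),
                    levels = prob$classes)
  fold <- stratified_folds(y_trial, folds)

  n_base <- if (window == "movement") 100L else 50L
  fold_curves <- NULL
  end_index <- NULL
  for (f in seq_len(folds)) {
    tr_prob <- prob; tr_prob$trials <- prob$trials[fold != f]
    te_prob <- prob; te_prob$trials <- prob$trials[fold == f]
    if (permute_labels) {
      labs <- vapply(tr_prob$trials, `[[`, "", "final_id")
      labs <- labs[sample(length(labs))]
      for (i in seq_along(tr_prob$trials))
        tr_prob$trials[[i]]$final_id <- labs[i]
    }
    te_data <- build_goal_dataset(te_prob, chunk_len, stride = 1,
                                  window = window)
    if (mode == "pooled") {
      tr_data <- build_goal_dataset(tr_prob, chunk_len, stride = train_stride,
                                    window = window)
      fit <- gru_fit(tr_data$x, tr_data$y, units = units, epochs = epochs,
                     patience = patience, learning_rate = learning_rate,
                     batch_size = batch_size,
                     validation_split = validation_split)
      curve <- evaluate_accuracy_curve(fit, te_data)
    } else {
      tr_data <- build_goal_dataset(tr_prob, chunk_len, stride = train_stride,
                                    window = window)
      nodes <- sort(unique(tr_data$end_index))
      acc <- vapply(nodes, function(e) {
        sel <- tr_data$end_index == e
        fit <- gru_fit(tr_data$x[sel, , , drop = FALSE], tr_data$y[sel],
                       units = units, epochs = epochs, patience = patience,
                       learning_rate = learning_rate, batch_size = batch_size,
                       validation_split = validation_split)
        tsel <- te_data$end_index == e
        mean(predict(fit, te_data$x[tsel, , , drop = FALSE], type = "class") ==
               as.character(te_data$y[tsel]))
      }, numeric(1))
      curve <- data.frame(end_index = nodes, accuracy = acc)
    }
    if (is.null(end_index)) {
      end_index <- curve$end_index
      fold_curves <- matrix(NA_real_, folds, length(end_index))
    }
    fold_curves[f, ] <- curve$accuracy
  }
  mean_curve <- colMeans(fold_curves)
  pct <- end_index / (n_base - 1) * 100

  structure(list(curve = data.frame(end_index = end_index,
                                    pct_movement = pct,
                                    accuracy = mean_curve),
                 fold_curves = fold_curves,
                 fold = fold,
                 chance = chance_level(length(prob$classes)),
                 classes = prob$classes,
                 dimension = dimension, problem = problem, window = window,
                 participant_id = session$participant_id,
                 n_trials = length(prob$trials),
                 settings = list(folds = folds, chunk_len = chunk_len,
                                 train_stride = train_stride, mode = mode,
                                 units = units, epochs = epochs,
                                 patience = patience,
                                 permute_labels = permute_labels)),
            class = "goal_decoding")
}

#' @export
print.goal_decoding <- function(x, ...) {
  cat(sprintf("Goal decoding '%s' (%s, %s window): %d trials, %d classes, %d folds\n",
              x$problem, x$dimension, x$window, x$n_trials,
              length(x$classes), x$settings$folds))
  cat(sprintf("  accuracy: max %.3f, mean %.3f (chance %.2f)\n",
              max(x$curve$accuracy), mean(x$curve$accuracy), x$chance))
  invisible(x)
}

#' @export
plot.goal_decoding <- function(x, ...) {
  xv <- if (x$window == "movement") x$curve$pct_movement else x$curve$end_index
  xl <- if (x$window == "movement") "% of movement" else "end index (pre-movement samples)"
  graphics::matplot(xv, t(x$fold_curves), type = "l", lty = 3,
                    col = "grey70", ylim = c(0, 1),
                    xlab = xl, ylab = "classification accuracy", ...)
  graphics::lines(xv, x$curve$accuracy, lwd = 2)
  graphics::abline(h = x$chance, lty = 2)
  invisible(x)
}

#' Select the trials of a target cluster
#'
#' A cluster pools a static target with its two shifted children: the static
#' trials to that target plus the shifted trials ending on either child.
#'
#' @param session A `reach_session`.
#' @param cluster `"left"`, `"right"`, `"near"` or `"far"`.
#' @return List of `reach_trial` objects.
#' @export
cluster_trials <- function(session, cluster = c("left", "right", "near", "far")) {
  cluster <- match.arg(cluster)
  children <- names(session$layout$parent)[session$layout$parent == cluster]
  Filter(function(tr) tr$final_id %in% c(cluster, children), session$trials)
}

# Chunked regression dataset: targets are the 6 feature values `offset`
# normalized time steps after each chunk's last sample; chunks whose future
# sample falls outside the trial are dropped.
build_regression_dataset <- function(trials, offset, chunk_len = 8,
                                     stride = 4) {
  feats <- lapply(trials, normalize_trial)
  n_samp <- nrow(feats[[1]])
  xs <- list(); ys <- list(); ends <- list(); tr_id <- list()
  for (i in seq_along(feats)) {
    ch <- extract_chunks(feats[[i]], chunk_len, stride)
    keep <- ch$end_index + offset <= n_samp - 1L
    if (!any(keep)) next
    xs[[i]] <- ch$chunks[keep]
    ends[[i]] <- ch$end_index[keep]
    ys[[i]] <- feats[[i]][ch$end_index[keep] + offset + 1L, , drop = FALSE]
    tr_id[[i]] <- rep(i, sum(keep))
  }
  chunks <- do.call(c, xs)
  if (length(chunks) == 0)
    stop("offset ", offset, " leaves no valid chunks")
  x <- array(NA_real_, c(length(chunks), chunk_len, 6))
  for (i in seq_along(chunks)) x[i, , ] <- chunks[[i]]
  list(x = x, y = do.call(rbind, ys),
       end_index = unlist(ends), trial = unlist(tr_id))
}

#' Coefficient of determination of a trajectory regressor
#'
#' Per-component R-squared pooled over all valid test chunks:
#' \eqn{R^2_k = 1 - SS_{res,k} / SS_{tot,k}} with the total sum of squares
#' around the test-set mean of component k.
#'
#' @param model A [gru_fit()] regressor, or a function mapping the chunk
#'   array to an `n x 6` prediction matrix.
#' @param dataset From `build_regression_dataset()`.
#' @return Named numeric vector of 6 R-squared values
#'   (`ix, iy, iz, wx, wy, wz`).
#' @export
evaluate_r2 <- function(model, dataset) {
  pred <- if (is.function(model)) model(dataset$x)
          else predict(model, dataset$x, type = "response")
  truth <- dataset$y
  ss_res <- colSums((truth - pred)^2)
  ss_tot <- colSums(sweep(truth, 2, colMeans(truth))^2)
  r2 <- ifelse(ss_tot > 0, 1 - ss_res / ss_tot,
               as.numeric(ss_res <= 1e-12))
  names(r2) <- FEATURES
  r2
}

#' Cross-validated regression of future trajectory values
#'
#' For each requested offset, GRU regressors are trained (per fold) to map a
#' chunk of past kinematics to the 6 kinematic values `offset` normalized
#' time steps after the chunk's last sample — i.e. to predict the hand's
#' position 4-30% of the movement into the future. Trials are those of one
#' target cluster (a static target and its two shifted children). R-squared
#' is computed per component on the pooled held-out chunks (unit inference
#' stride) and averaged across folds.
#'
#' @param session A `reach_session`.
#' @param cluster Target cluster, see [cluster_trials()].
#' @param offsets Future offsets in normalized time steps (percent of
#'   movement), default `c(4, 6, 8, 10, 12, 20, 30)`.
#' @param folds Cross-validation folds (stratified on final endpoint).
#' @param chunk_len,train_stride Chunking as in [decode_goals()].
#' @param units,epochs,patience,learning_rate,batch_size,validation_split
#'   Passed to [gru_fit()].
#' @param seed Optional integer seed.
#' @return An object of class `trajectory_decoding`: `r2` (offsets x 6
#'   fold-averaged matrix), `r2_index` (offsets x 3, fingertip components
#'   only), `per_fold` (list of folds x 6 matrices), `cluster`, `offsets`.
#' @export
decode_trajectory <- function(session,
                              cluster = c("left", "right", "near", "far"),
                              offsets = c(4, 6, 8, 10, 12, 20, 30),
                              folds = 5, chunk_len = 8, train_stride = 4,
                              units = 100, epochs = 500, patience = 50,
                              learning_rate = 0.001, batch_size = 32,
                              validation_split = 0.2, seed = NULL) {
  cluster <- match.arg(cluster)
  if (!is.null(seed)) set.seed(seed)
  trials <- cluster_trials(session, cluster)
  if (length(trials) < folds) stop("too few trials in cluster")
  y_trial <- factor(vapply(trials, `[[`, "", "final_id"))
  fold <- stratified_folds(y_trial, folds)

  r2 <- matrix(NA_real_, length(offsets), 6,
               dimnames = list(offsets, FEATURES))
  per_fold <- vector("list", length(offsets))
  names(per_fold) <- offsets
  for (oi in seq_along(offsets)) {
    off <- offsets[oi]
    fr2 <- matrix(NA_real_, folds, 6)
    for (f in seq_len(folds)) {
      tr_data <- build_regression_dataset(trials[fold != f], off,
                                          chunk_len, train_stride)
      te_data <- build_regression_dataset(trials[fold == f], off,
                                          chunk_len, stride = 1)
      fit <- gru_fit(tr_data$x, tr_data$y, type = "regression",
                     units = units, epochs = epochs, patience = patience,
                     learning_rate = learning_rate, batch_size = batch_size,
                     validation_split = validation_split)
      fr2[f, ] <- evaluate_r2(fit, te_data)
    }
    per_fold[[oi]] <- fr2
    r2[oi, ] <- colMeans(fr2)
  }
  structure(list(r2 = r2, r2_index = r2[, 1:3, drop = FALSE],
                 per_fold = per_fold, cluster = cluster, offsets = offsets,
                 n_trials = length(trials),
                 settings = list(folds = folds, chunk_len = chunk_len,
                                 train_stride = train_stride, units = units,
                                 epochs = epochs, patience = patience)),
            class = "trajectory_decoding")
}

#' @export
print.trajectory_decoding <- function(x, ...) {
  cat(sprintf("Trajectory decoding, cluster '%s' (%d trials, %d folds)\n",
              x$cluster, x$n_trials, x$settings$folds))
  cat("  fold-averaged R^2 (fingertip x, y, z):\n")
  print(round(x$r2_index, 3))
  invisible(x)
}

#' @export
plot.trajectory_decoding <- function(x, ...) {
  graphics::matplot(x$offsets, x$r2_index, type = "b", pch = 1:3,
                    xlab = "offset (% of movement)",
                    ylab = expression(R^2), ylim = c(0, 1), ...)
  graphics::legend("bottomleft", legend = c("x", "y", "z"), pch = 1:3,
                   col = 1:3, lty = 1:3, bty = "n")
  invisible(x)
}
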