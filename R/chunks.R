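FEATURES <- c("ix", "iy", "iz", "wx", "wy", "wz")

#' Normalize a trial's movement kinematics to 100 time steps
#'
#' Resamples the six kinematic series (fingertip x, y, z; wrist x, y, z) of
#' the movement segment onto 100 equally spaced points of normalized movement
#' time (0-100% between onset and touch), by linear interpolation.
#'
#' @param trial A `reach_trial`.
#' @param n_samples Number of normalized time steps (default 100).
#' @return A `n_samples x 6` matrix with columns
#'   `ix, iy, iz, wx, wy, wz` (cm).
#' @export
normalize_trial <- function(trial, n_samples = 100) {
  seg_i <- movement_segment(trial, "index")
  seg_w <- movement_segment(trial, "wrist")
  if (length(seg_i$t) < 2) stop("degenerate movement segment")
  xout <- seq(seg_i$t[1], seg_i$t[length(seg_i$t)], length.out = n_samples)
  out <- matrix(NA_real_, n_samples, 6, dimnames = list(NULL, FEATURES))
  for (k in 1:3) {
    out[, k] <- stats::approx(seg_i$t, seg_i$xyz[, k], xout = xout)$y
    out[, k + 3] <- stats::approx(seg_w$t, seg_w$xyz[, k], xout = xout)$y
  }
  out
}

# The 50-sample (500 ms at 100 Hz) window immediately preceding movement
# onset, un-normalized; used to test for predictive micro-movements.
pre_movement_features <- function(trial, n_samples = 50) {
  ev <- trial$events
  eps <- 1e-9
  keep <- which(trial$t < ev$movement_onset_s - eps)
  if (length(keep) < n_samples)
    stop("trial has fewer than ", n_samples, " pre-movement samples")
  keep <- utils::tail(keep, n_samples)
  cbind(trial$index_xyz[keep, , drop = FALSE],
        trial$wrist_xyz[keep, , drop = FALSE]) |>
    `colnames<-`(FEATURES)
}

#' Extract sliding-window chunks from a normalized trial
#'
#' Cuts a feature matrix into windows of `chunk_len` consecutive time steps,
#' sliding by `stride`. Each chunk records the 0-based index of its last
#' sample (`end_index`) within the source matrix; with the defaults
#' (100 samples, `chunk_len = 8`) a stride of 4 yields 24 chunks and a stride
#' of 1 yields 93.
#'
#' @param mat A time x feature matrix (e.g. from [normalize_trial()]).
#' @param chunk_len Window length T in time steps (default 8).
#' @param stride Slide between consecutive windows (>= 1).
#' @return A list with `chunks` (list of `chunk_len x K` matrices) and
#'   `end_index` (integer vector, 0-based).
#' @export
extract_chunks <- function(mat, chunk_len = 8, stride = 4) {
  n <- nrow(mat)
  if (chunk_len > n) stop("'chunk_len' exceeds the number of samples")
  if (stride < 1) stop("'stride' must be >= 1")
  starts <- seq(1, n - chunk_len + 1, by = stride)
  list(chunks = lapply(starts, function(s) mat[s:(s + chunk_len - 1), , drop = FALSE]),
       end_index = as.integer(starts + chunk_len - 2L))
}

#' Define a goal-decoding problem on a session
#'
#' Selects the trials and endpoint classes for one of the goal-classification
#' problems within a dimension:
#' * `"static"` — the two static targets of the dimension (2 classes);
#' * `"shifted_left"`, `"shifted_right"` (horizontal) and `"shifted_near"`,
#'   `"shifted_far"` (sagittal) — the two shifted children of one static
#'   target (2 classes);
#' * `"sixway"` — all 6 endpoints of the dimension (2 static + 4 shifted).
#'
#' @param session A `reach_session`.
#' @param dimension `"horizontal"` or `"sagittal"`.
#' @param problem One of the problem names above.
#' @return An object of class `decoding_problem`: `trials` (selected
#'   `reach_trial`s), `classes` (endpoint ids), `dimension`, `problem`.
#' @export
decoding_problem <- function(session,
                             dimension = c("horizontal", "sagittal"),
                             problem = c("static", "shifted_left",
                                         "shifted_right", "shifted_near",
                                         "shifted_far", "sixway")) {
  dimension <- match.arg(dimension)
  problem <- match.arg(problem)
  lay <- session$layout
  statics <- rownames(lay$static_targets)
  statics <- statics[endpoint_dimension(statics) == dimension]
  parent_of <- sub("shifted_", "", problem)
  if (problem %in% c("shifted_left", "shifted_right", "shifted_near",
                     "shifted_far")) {
    if (!parent_of %in% statics)
      stop(sprintf("problem '%s' is not defined for the %s dimension",
                   problem, dimension))
    classes <- names(lay$parent)[lay$parent == parent_of]
  } else if (problem == "static") {
    classes <- statics
  } else {
    classes <- c(statics, names(lay$parent)[lay$parent %in% statics])
  }
  trials <- Filter(function(tr) tr$final_id %in% classes, session$trials)
  if (length(trials) == 0) stop("no trials match this problem")
  structure(list(trials = trials, classes = classes,
                 dimension = dimension, problem = problem),
            class = "decoding_problem")
}

#' @export
print.decoding_problem <- function(x, ...) {
  y <- vapply(x$trials, `[[`, "", "final_id")
  cat(sprintf("decoding_problem '%s' (%s): %d trials, %d classes\n",
              x$problem, x$dimension, length(x$trials), length(x$classes)))
  print(table(factor(y, levels = x$classes)))
  invisible(x)
}

#' Build a chunked goal-classification dataset
#'
#' Turns the trials of a [decoding_problem()] into sliding-window chunks with
#' class labels. Every chunk of a trial inherits the trial's final endpoint as
#' its label. The `"movement"` window uses the movement segment normalized to
#' 100 samples; `"pre_movement"` uses the raw 500 ms (50 samples) preceding
#' movement onset.
#'
#' @param problem A `decoding_problem` (or list of `reach_trial`s plus
#'   `classes` attribute).
#' @param chunk_len,stride Chunking parameters (see [extract_chunks()]).
#' @param window `"movement"` or `"pre_movement"`.
#' @return A list with `x` (array `n_chunks x chunk_len x 6`), `y` (factor of
#'   endpoint classes), `end_index` (0-based), `trial` (index of the source
#'   trial within `problem$trials`), `trial_labels` (factor, one per trial).
#' @export
build_goal_dataset <- function(problem, chunk_len = 8, stride = 4,
                               window = c("movement", "pre_movement")) {
  window <- match.arg(window)
  trials <- problem$trials
  classes <- problem$classes
  feats <- lapply(trials, function(tr) {
    if (window == "movement") normalize_trial(tr) else pre_movement_features(tr)
  })
  ch <- lapply(feats, extract_chunks, chunk_len = chunk_len, stride = stride)
  n_per <- vapply(ch, function(c.) length(c.$chunks), 0L)
  x <- array(NA_real_, c(sum(n_per), chunk_len, 6))
  i <- 0L
  for (c. in ch) for (m in c.$chunks) { i <- i + 1L; x[i, , ] <- m }
  y_trial <- factor(vapply(trials, `[[`, "", "final_id"), levels = classes)
  list(x = x,
       y = rep(y_trial, n_per),
       end_index = unlist(lapply(ch, `[[`, "end_index"), use.names = FALSE),
       trial = rep(seq_along(trials), n_per),
       trial_labels = y_trial)
}

#' Theoretical chance level of a balanced classification
#'
#' @param n_classes Number of classes (>= 2).
#' @return `1 / n_classes` (e.g. 0.5 for pairwise problems; 0.1667, displayed
#'   as 0.16, for the 6-way problems).
#' @export
chance_level <- function(n_classes) {
  if (!is.numeric(n_classes) || length(n_classes) != 1 || n_classes < 2)
    stop("'n_classes' must be >= 2")
  1 / n_classes
}

#' Stratified k-fold assignment at the trial level
#'
#' Assigns trials to `k` folds so that each class is spread as evenly as
#' possible across folds (round-robin over a seeded shuffle within class).
#' With 60 trials in 2 balanced classes and `k = 5`, every fold holds 12 test
#' trials (6 per class) against 48 training trials.
#'
#' @param labels Factor (or vector) of per-trial class labels.
#' @param k Number of folds.
#' @return Integer vector of fold ids in `1:k`, one per trial.
#' @export
stratified_folds <- function(labels, k = 5) {
  labels <- as.factor(labels)
  if (any(table(labels) < k))
    stop("cannot stratify: some class has fewer trials than folds")
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(sample.int(k), length(idx))
  }
  fold
}
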