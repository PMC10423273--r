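#' Movement segment of a trial
#'
#' Extracts the fingertip samples between movement onset and screen touch
#' (inclusive bounds on the 100 Hz grid).
#'
#' @param trial A `reach_trial`.
#' @param marker `"index"` or `"wrist"`.
#' @return A list with `t` (seconds) and `xyz` (n x 3 matrix, cm); the first
#'   sample is at movement onset.
#' @export
movement_segment <- function(trial, marker = c("index", "wrist")) {
  marker <- match.arg(marker)
  ev <- trial$events
  if (is.null(ev$movement_onset_s) || is.null(ev$touch_s) ||
      is.na(ev$movement_onset_s) || is.na(ev$touch_s))
    stop("trial is missing movement onset or touch event")
  if (ev$touch_s <= ev$movement_onset_s)
    stop("malformed trial: touch at or before movement onset")
  eps <- 1e-9
  keep <- trial$t >= ev$movement_onset_s - eps & trial$t <= ev$touch_s + eps
  if (!any(keep)) stop("empty movement segment")
  xyz <- if (marker == "index") trial$index_xyz else trial$wrist_xyz
  list(t = trial$t[keep], xyz = xyz[keep, , drop = FALSE])
}

# Central-difference derivative (one-sided at the ends) at uniform spacing.
finite_diff <- function(x, dt) {
  n <- length(x)
  if (n < 3) stop("need at least 3 samples to differentiate")
  v <- numeric(n)
  v[1] <- (x[2] - x[1]) / dt
  v[n] <- (x[n] - x[n - 1]) / dt
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  v
}

#' Lateral velocity of a trial
#'
#' Time derivative of the fingertip's horizontal (x) coordinate over the
#' movement segment, by central differences at the trial's sampling rate,
#' optionally smoothed with a centred moving average. Time stamps are
#' reported relative to the target shift for shifted trials and relative to
#' movement onset for static trials.
#'
#' @param trial A `reach_trial`.
#' @param smooth_window Width (samples) of the centred moving average; 0 or 1
#'   disables smoothing (default).
#' @return A data frame with `t_rel_ms` and `v_lat` (cm/s), plus attributes
#'   `align` (`"shift"` or `"onset"`) and `dt_ms`.
#' @export
lateral_velocity <- function(trial, smooth_window = 0) {
  seg <- movement_segment(trial)
  if (length(seg$t) < 3) stop("trial too short for velocity estimation")
  dt <- seg$t[2] - seg$t[1]
  v <- finite_diff(seg$xyz[, 1], dt)
  if (smooth_window > 1) {
    k <- rep(1 / smooth_window, smooth_window)
    v <- stats::filter(v, k, sides = 2)
    v <- as.numeric(v)
    # shrink the window at the edges instead of dropping samples
    half <- floor(smooth_window / 2)
    n <- length(v)
    for (i in which(is.na(v))) {
      lo <- max(1, i - half); hi <- min(n, i + half)
      v[i] <- mean(finite_diff(seg$xyz[, 1], dt)[lo:hi])
    }
  }
  ref <- if (trial$condition == "shifted" && !is.na(trial$events$shift_s))
    trial$events$shift_s else trial$events$movement_onset_s
  out <- data.frame(t_rel_ms = (seg$t - ref) * 1000, v_lat = v)
  attr(out, "align") <- if (ref == trial$events$movement_onset_s) "onset" else "shift"
  attr(out, "dt_ms") <- dt * 1000
  out
}

#' Stack lateral-velocity traces of several trials on a common time base
#'
#' Traces are aligned on their reference event (target shift for shifted
#' trials, movement onset for static trials) and truncated to the time range
#' common to all trials in the group.
#'
#' @param trials List of `reach_trial` objects.
#' @param smooth_window Passed to [lateral_velocity()].
#' @return A list with `t_ms` (common time stamps) and `v` (trials x time
#'   matrix of lateral velocities, cm/s).
#' @export
velocity_traces <- function(trials, smooth_window = 0) {
  if (length(trials) < 1) stop("need at least one trial")
  vs <- lapply(trials, lateral_velocity, smooth_window = smooth_window)
  dt <- attr(vs[[1]], "dt_ms")
  lo <- max(vapply(vs, function(v) min(v$t_rel_ms), 0))
  hi <- min(vapply(vs, function(v) max(v$t_rel_ms), 0))
  if (hi < lo) stop("trials share no common aligned time range")
  t_ms <- seq(ceiling(lo / dt) * dt, floor(hi / dt) * dt, by = dt)
  v <- t(vapply(vs, function(vd) {
    stats::approx(vd$t_rel_ms, vd$v_lat, xout = t_ms)$y
  }, numeric(length(t_ms))))
  list(t_ms = t_ms, v = v)
}

# Per-column Welch two-sample t statistic and two-sided p-value.
col_welch <- function(a, b) {
  n1 <- nrow(a); n2 <- nrow(b)
  m1 <- colMeans(a); m2 <- colMeans(b)
  v1 <- apply(a, 2, stats::var); v2 <- apply(b, 2, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  p[!is.finite(tt)] <- 1
  list(t = tt, p = p)
}

#' Detect the deviation (correction) time between two groups of traces
#'
#' Compares two groups of lateral-velocity traces sample by sample with a
#' two-tailed Welch t-test and reports the first sample at or after the
#' alignment zero that begins a run of at least `run_length` consecutive
#' significant samples (p < `alpha`). This is the correction-onset estimator:
#' applied to the left- and right-shifted (or near-/far-shifted) trials of a
#' session it gives the time, relative to the target shift, at which the two
#' corrected trajectories become statistically separable.
#'
#' @param traces_a,traces_b Either results of [velocity_traces()] or plain
#'   numeric matrices (trials x time) on a common time base. Matrices of
#'   unequal width are truncated to the shorter.
#' @param t_ms Time stamps (ms) for matrix input; defaults to 10 ms samples
#'   starting at 0.
#' @param alpha Per-sample significance level (default 0.05, two-tailed).
#' @param run_length Required run of consecutive significant samples
#'   (default 10, i.e. 100 ms of sustained separation at 100 Hz); 1
#'   reproduces the single-significant-sample criterion.
#' @return An object of class `deviation_result`: `deviation_time_ms` (or
#'   `NA` if no run is found), `t_ms`, `p` (per-sample p-values), `alpha`,
#'   `run_length`, group sizes.
#' @export
detect_deviation_time <- function(traces_a, traces_b, t_ms = NULL,
                                  alpha = 0.05, run_length = 10) {
  unpack <- function(x) {
    if (is.list(x) && !is.null(x$v)) list(v = x$v, t = x$t_ms)
    else list(v = as.matrix(x), t = NULL)
  }
  a <- unpack(traces_a); b <- unpack(traces_b)
  if (nrow(a$v) < 2 || nrow(b$v) < 2)
    stop("need at least 2 traces per group")
  if (!is.null(a$t) && !is.null(b$t)) {
    dt_a <- diff(a$t[1:2]); dt_b <- diff(b$t[1:2])
    if (abs(dt_a - dt_b) > 1e-6) stop("mismatched sampling rates")
    lo <- max(a$t[1], b$t[1]); hi <- min(max(a$t), max(b$t))
    ka <- a$t >= lo - 1e-9 & a$t <= hi + 1e-9
    kb <- b$t >= lo - 1e-9 & b$t <= hi + 1e-9
    a$v <- a$v[, ka, drop = FALSE]; b$v <- b$v[, kb, drop = FALSE]
    t_ms <- a$t[ka]
  } else {
    m <- min(ncol(a$v), ncol(b$v))
    a$v <- a$v[, 1:m, drop = FALSE]; b$v <- b$v[, 1:m, drop = FALSE]
    if (is.null(t_ms)) t_ms <- (seq_len(m) - 1) * 10
    else t_ms <- t_ms[1:m]
  }
  w <- col_welch(a$v, b$v)
  sig <- w$p < alpha
  eligible <- t_ms >= 0
  dev <- NA_real_
  idx <- which(eligible)
  n <- length(sig)
  for (i in idx) {
    if (i + run_length - 1 > n) break
    if (all(sig[i:(i + run_length - 1)])) { dev <- t_ms[i]; break }
  }
  structure(list(deviation_time_ms = dev, t_ms = t_ms, p = w$p,
                 statistic = w$t, alpha = alpha, run_length = run_length,
                 n_a = nrow(a$v), n_b = nrow(b$v)),
            class = "deviation_result")
}

#' @export
print.deviation_result <- function(x, ...) {
  cat(sprintf("Deviation-time detection (%d vs %d traces, alpha %.3g, run %d)\n",
              x$n_a, x$n_b, x$alpha, x$run_length))
  if (is.na(x$deviation_time_ms)) cat("  no sustained significant deviation\n")
  else cat(sprintf("  deviation at %.0f ms\n", x$deviation_time_ms))
  invisible(x)
}

#' Endpoint accuracy (reaching error)
#'
#' Euclidean distance, on the screen plane, between the recorded touch point
#' and the target location:
#' \deqn{error = \sqrt{(x_M - x_{loc})^2 + (y_M - y_{loc})^2}.}
#'
#' @param touch_xy Touch coordinates: length-2 vector or n x 2 matrix (cm).
#' @param target_xy Target coordinates, same shape rules.
#' @return Non-negative distance(s) in cm.
#' @examples
#' endpoint_error(c(3, 4), c(0, 0))  # 5
#' @export
endpoint_error <- function(touch_xy, target_xy) {
  touch <- rbind(touch_xy); target <- rbind(target_xy)
  if (ncol(touch) != 2 || ncol(target) != 2)
    stop("coordinates must have 2 columns (x, y)")
  if (any(!is.finite(touch)) || any(!is.finite(target)))
    stop("coordinates must be finite")
  d <- touch - target[rep_len(seq_len(nrow(target)), nrow(touch)), , drop = FALSE]
  unname(sqrt(rowSums(d^2)))
}

#' Reaction time of a trial
#'
#' Interval between the appearance of the reach target (cue) and movement
#' onset, in milliseconds.
#'
#' @param trial A `reach_trial`.
#' @return Reaction time in ms (> 0).
#' @export
reaction_time <- function(trial) {
  ev <- trial$events
  if (is.null(ev$cue_on_s) || is.null(ev$movement_onset_s) ||
      is.na(ev$cue_on_s) || is.na(ev$movement_onset_s))
    stop("trial is missing cue or movement-onset event")
  rt <- (ev$movement_onset_s - ev$cue_on_s) * 1000
  if (rt <= 0) stop("malformed trial: movement onset before cue")
  rt
}

#' Across-trial trajectory variability at peak velocity
#'
#' For each trial, finds the time of maximum 3D fingertip speed within the
#' movement and takes the `axis` coordinate there; returns the across-trial
#' standard deviation of those coordinates (cm). Used to compare motor
#' strategies across conditions/experiments at a kinematically relevant
#' landmark.
#'
#' @param trials List of `reach_trial` objects (>= 2).
#' @param axis `"x"` or `"y"`.
#' @return Sample standard deviation (cm).
#' @export
peak_velocity_variability <- function(trials, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (length(trials) < 2) stop("need at least 2 trials")
  coord <- vapply(trials, function(tr) {
    seg <- movement_segment(tr)
    dt <- seg$t[2] - seg$t[1]
    sp <- sqrt(rowSums(apply(seg$xyz, 2, finite_diff, dt = dt)^2))
    seg$xyz[which.max(sp), match(axis, c("x", "y"))]
  }, numeric(1))
  stats::sd(coord)
}

#' Movement durations and mean speeds per condition
#'
#' Aggregates movement duration and mean 3D fingertip speed over the movement
#' segment, per condition (static/shifted), for a session or a list of trials.
#'
#' @param session A `reach_session`, or a list of `reach_trial` objects.
#' @return A list with `trials` (one row per trial: condition, dimension,
#'   duration_s, mean_speed_cm_s) and `by_condition` (group means and SDs).
#' @export
movement_summary <- function(session) {
  trials <- if (inherits(session, "reach_session")) session$trials else session
  if (length(trials) == 0) stop("no trials")
  rows <- do.call(rbind, lapply(trials, function(tr) {
    seg <- movement_segment(tr)
    dt <- seg$t[2] - seg$t[1]
    sp <- sqrt(rowSums(apply(seg$xyz, 2, finite_diff, dt = dt)^2))
    data.frame(trial_id = tr$trial_id, condition = tr$condition,
               dimension = tr$dimension,
               duration_s = tr$events$touch_s - tr$events$movement_onset_s,
               mean_speed_cm_s = mean(sp), stringsAsFactors = FALSE)
  }))
  agg <- do.call(rbind, lapply(split(rows, rows$condition), function(g) {
    data.frame(condition = g$condition[1], n = nrow(g),
               mean_duration_s = mean(g$duration_s),
               sd_duration_s = stats::sd(g$duration_s),
               mean_speed_cm_s = mean(g$mean_speed_cm_s),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  list(trials = rows, by_condition = agg)
}
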