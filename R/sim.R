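#' Simulation parameters for double-step reaching sessions
#'
#' Collects every tunable of the trial generator. Defaults emulate the task
#' conditions of a perturbation-at-movement-onset experiment: a 1.5 s fixation
#' period, reaction times around 350 ms, movement durations around 630 ms,
#' dimension-specific online-correction latencies, and small marker/endpoint
#' noise. Use [experiment_params()] for the per-experiment presets.
#'
#' @param shift_latency_ms Delay (ms) of the target shift after movement
#'   onset: 0 (shift at onset) or 100.
#' @param movement_duration_mean_ms,movement_duration_sd_ms,movement_duration_min_ms
#'   Truncated-normal movement duration (ms).
#' @param reaction_time_mean_ms,reaction_time_sd_ms,reaction_time_min_ms
#'   Truncated-normal reaction time (ms) from target cue to movement onset.
#' @param correction_latency_horizontal_ms,correction_latency_sagittal_ms
#'   Length-2 numeric `c(mean, sd)` (ms): latency from target shift to the
#'   start of the corrective submovement, per shift dimension.
#' @param p_no_correction_sagittal Probability in `[0, 1]` that a sagittal
#'   shifted trial is never corrected (the hand completes the original reach).
#' @param position_noise_sd_cm Per-sample i.i.d. Gaussian noise on each marker
#'   coordinate (cm).
#' @param endpoint_sd_cm SD (cm) of the touch-point scatter around the planned
#'   endpoint.
#' @param wrist_offset_cm Length-3 offset (cm) of the wrist marker relative to
#'   the fingertip.
#' @param start_pos_cm Length-3 hand start position (cm; screen plane z = 0,
#'   fixation at the origin, +y away from the body).
#' @param start_jitter_sd_cm SD (cm) of the per-trial start-position jitter.
#' @param lift_height_cm Peak height (cm) of the vertical movement arc.
#' @param fixation_s Fixation period (s) before the reach cue.
#' @param sample_rate_hz Marker sampling rate (Hz), default 100.
#' @return An object of class `sim_params` (a validated list).
#' @seealso [simulate_trial()], [simulate_session()]
#' @export
sim_params <- function(shift_latency_ms = 0,
                       movement_duration_mean_ms = 630,
                       movement_duration_sd_ms = 60,
                       movement_duration_min_ms = 400,
                       reaction_time_mean_ms = 350,
                       reaction_time_sd_ms = 50,
                       reaction_time_min_ms = 150,
                       correction_latency_horizontal_ms = c(195, 25),
                       correction_latency_sagittal_ms = c(290, 25),
                       p_no_correction_sagittal = 0,
                       position_noise_sd_cm = 0.05,
                       endpoint_sd_cm = 0.4,
                       wrist_offset_cm = c(-1, -7, 1),
                       start_pos_cm = c(0, -25, 0),
                       start_jitter_sd_cm = 0.3,
                       lift_height_cm = 3,
                       fixation_s = 1.5,
                       sample_rate_hz = 100) {
  p <- list(shift_latency_ms = shift_latency_ms,
            movement_duration_mean_ms = movement_duration_mean_ms,
            movement_duration_sd_ms = movement_duration_sd_ms,
            movement_duration_min_ms = movement_duration_min_ms,
            reaction_time_mean_ms = reaction_time_mean_ms,
            reaction_time_sd_ms = reaction_time_sd_ms,
            reaction_time_min_ms = reaction_time_min_ms,
            correction_latency_horizontal_ms = correction_latency_horizontal_ms,
            correction_latency_sagittal_ms = correction_latency_sagittal_ms,
            p_no_correction_sagittal = p_no_correction_sagittal,
            position_noise_sd_cm = position_noise_sd_cm,
            endpoint_sd_cm = endpoint_sd_cm,
            wrist_offset_cm = wrist_offset_cm,
            start_pos_cm = start_pos_cm,
            start_jitter_sd_cm = start_jitter_sd_cm,
            lift_height_cm = lift_height_cm,
            fixation_s = fixation_s,
            sample_rate_hz = sample_rate_hz)
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  sds <- c(p$movement_duration_sd_ms, p$reaction_time_sd_ms,
           p$correction_latency_horizontal_ms[2],
           p$correction_latency_sagittal_ms[2],
           p$position_noise_sd_cm, p$endpoint_sd_cm, p$start_jitter_sd_cm)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("all standard deviations must be finite and >= 0")
  if (!is.finite(p$p_no_correction_sagittal) ||
      p$p_no_correction_sagittal < 0 || p$p_no_correction_sagittal > 1)
    stop("'p_no_correction_sagittal' must be a probability in [0, 1]")
  if (!is.finite(p$sample_rate_hz) || p$sample_rate_hz <= 0)
    stop("'sample_rate_hz' must be > 0")
  if (!p$shift_latency_ms >= 0)
    stop("'shift_latency_ms' must be >= 0")
  if (length(p$wrist_offset_cm) != 3 || length(p$start_pos_cm) != 3)
    stop("'wrist_offset_cm' and 'start_pos_cm' must have length 3")
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Double-step simulation parameters\n")
  cat(sprintf("  shift latency      : %g ms after movement onset\n",
              x$shift_latency_ms))
  cat(sprintf("  correction latency : horizontal %g +/- %g ms, sagittal %g +/- %g ms\n",
              x$correction_latency_horizontal_ms[1],
              x$correction_latency_horizontal_ms[2],
              x$correction_latency_sagittal_ms[1],
              x$correction_latency_sagittal_ms[2]))
  cat(sprintf("  P(no sagittal correction): %g\n", x$p_no_correction_sagittal))
  cat(sprintf("  movement duration  : %g +/- %g ms (min %g)\n",
              x$movement_duration_mean_ms, x$movement_duration_sd_ms,
              x$movement_duration_min_ms))
  cat(sprintf("  noise              : position %g cm, endpoint %g cm\n",
              x$position_noise_sd_cm, x$endpoint_sd_cm))
  invisible(x)
}

#' Per-experiment simulation presets
#'
#' Experiment 1: target shift at movement onset; online corrections in both
#' dimensions (horizontal latency ~195 ms, sagittal ~290 ms). Experiment 2:
#' shift 100 ms after onset; faster horizontal corrections (~140 ms) but no
#' correction at all for sagittal shifts, which is what produces the large
#' depth endpoint errors in that condition.
#'
#' @param experiment 1 or 2.
#' @param ... Overrides passed on to [sim_params()].
#' @return A `sim_params` object.
#' @export
experiment_params <- function(experiment, ...) {
  experiment <- as.integer(experiment)
  if (!experiment %in% c(1L, 2L)) stop("'experiment' must be 1 or 2")
  defaults <- if (experiment == 1L) {
    list(shift_latency_ms = 0,
         correction_latency_horizontal_ms = c(195, 25),
         correction_latency_sagittal_ms = c(290, 25),
         p_no_correction_sagittal = 0)
  } else {
    list(shift_latency_ms = 100,
         correction_latency_horizontal_ms = c(140, 25),
         correction_latency_sagittal_ms = c(290, 25),
         p_no_correction_sagittal = 1)
  }
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_params, args)
}

rtrunc_norm <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(max(mean, lower), n))
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lower)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Simulate one double-step reaching trial
#'
#' Generates the 100 Hz fingertip and wrist trajectories of a single reach.
#' The hand rests at the (jittered) start position until movement onset, then
#' follows a minimum-jerk reach to the initially cued target with a vertical
#' lift arc. In shifted trials the target jumps `shift_latency_ms` after
#' onset; after a dimension-specific correction latency a second minimum-jerk
#' submovement toward the final target is superposed, completing at touch.
#' Sagittal trials may fail to correct (probability
#' `p_no_correction_sagittal`), as does any trial whose drawn latency leaves
#' no time to correct; such trials land near the initial target and are
#' flagged `corrected = FALSE`. I.i.d. Gaussian noise is added per sample, the
#' wrist is the fingertip plus a rigid offset plus independent noise, and the
#' recorded touch point is the planned endpoint plus endpoint noise.
#'
#' Randomness is drawn from R's global RNG; seed with [set.seed()] for
#' reproducible trials.
#'
#' @param layout A [target_layout()].
#' @param params A [sim_params()].
#' @param condition `"static"` or `"shifted"`.
#' @param initial_id Static endpoint id cued at movement start.
#' @param final_id Final endpoint id: equal to `initial_id` for static trials,
#'   a shifted child of it for shifted trials.
#' @param experiment Experiment label (1 or 2) stored on the trial.
#' @param participant_id,trial_id Identifiers stored on the trial.
#' @return An object of class `reach_trial`: a list with `t` (seconds, uniform
#'   at `1/sample_rate_hz`), `index_xyz` and `wrist_xyz` (n x 3 matrices, cm),
#'   `events` (`cue_on_s`, `movement_onset_s`, `shift_s`, `touch_s`),
#'   `endpoint_touch_xy`, `endpoint_planned_xy`, labels (`condition`,
#'   `dimension`, `initial_id`, `final_id`, ids) and the `corrected` flag.
#' @examples
#' set.seed(1)
#' tr <- simulate_trial(target_layout(), sim_params(), "static", "right")
#' tr$final_id
#' @export
simulate_trial <- function(layout, params, condition = c("static", "shifted"),
                           initial_id, final_id = initial_id,
                           experiment = 1L, participant_id = 1L,
                           trial_id = 1L) {
  condition <- match.arg(condition)
  stopifnot(inherits(layout, "target_layout"), inherits(params, "sim_params"))
  if (!initial_id %in% rownames(layout$static_targets))
    stop("'initial_id' must be a static endpoint id")
  if (condition == "static") {
    if (final_id != initial_id)
      stop("static trials must have final_id == initial_id")
  } else {
    if (!final_id %in% rownames(layout$shifted_targets) ||
        layout$parent[final_id] != initial_id)
      stop("shifted trials require 'final_id' to be a shifted child of 'initial_id'")
  }
  dimension <- endpoint_dimension(initial_id)
  fs <- params$sample_rate_hz
  dt <- 1 / fs

  rt_s <- rtrunc_norm(1, params$reaction_time_mean_ms,
                      params$reaction_time_sd_ms,
                      params$reaction_time_min_ms) / 1000
  dur_s <- rtrunc_norm(1, params$movement_duration_mean_ms,
                       params$movement_duration_sd_ms,
                       params$movement_duration_min_ms) / 1000
  cue_s <- params$fixation_s
  onset_s <- round((cue_s + rt_s) * fs) / fs
  touch_s <- onset_s + round(dur_s * fs) / fs

  start <- params$start_pos_cm + stats::rnorm(3, 0, params$start_jitter_sd_cm)
  init_target <- c(endpoint_position(layout, initial_id), 0)
  final_target <- c(endpoint_position(layout, final_id), 0)

  n <- round(touch_s * fs) + 1L
  t <- (seq_len(n) - 1L) * dt
  tau <- (t - onset_s) / (touch_s - onset_s)
  s1 <- min_jerk_profile(tau)
  path <- outer(s1, init_target - start)
  path <- sweep(path, 2, start, "+")
  path[, 3] <- path[, 3] +
    params$lift_height_cm * sin(pi * pmin(pmax(tau, 0), 1))

  corrected <- NA
  shift_s <- NA_real_
  corr_start_s <- NA_real_
  if (condition == "shifted") {
    shift_s <- onset_s + params$shift_latency_ms / 1000
    lat <- if (dimension == "horizontal") params$correction_latency_horizontal_ms
           else params$correction_latency_sagittal_ms
    corr_lat_s <- max(stats::rnorm(1, lat[1], lat[2]), 0) / 1000
    corr_start_s <- shift_s + corr_lat_s
    no_corr <- FALSE
    if (dimension == "sagittal" &&
        stats::runif(1) < params$p_no_correction_sagittal)
      no_corr <- TRUE
    # a latency that leaves (almost) no movement time cannot be corrected
    if (corr_start_s > touch_s - 2 * dt) no_corr <- TRUE
    corrected <- !no_corr
    if (corrected) {
      tau2 <- (t - corr_start_s) / (touch_s - corr_start_s)
      s2 <- min_jerk_profile(tau2)
      path <- path + outer(s2, final_target - init_target)
    }
  }

  planned_xy <- path[n, 1:2]
  touch_xy <- planned_xy + stats::rnorm(2, 0, params$endpoint_sd_cm)
  index <- path + matrix(stats::rnorm(3 * n, 0, params$position_noise_sd_cm),
                         n, 3)
  wrist <- sweep(path, 2, params$wrist_offset_cm, "+") +
    matrix(stats::rnorm(3 * n, 0, params$position_noise_sd_cm), n, 3)
  colnames(index) <- colnames(wrist) <- c("x", "y", "z")

  structure(list(trial_id = as.integer(trial_id),
                 participant_id = participant_id,
                 experiment = as.integer(experiment),
                 dimension = dimension,
                 condition = condition,
                 initial_id = initial_id,
                 final_id = final_id,
                 t = t,
                 index_xyz = index,
                 wrist_xyz = wrist,
                 events = list(cue_on_s = cue_s,
                               movement_onset_s = onset_s,
                               shift_s = shift_s,
                               touch_s = touch_s),
                 endpoint_touch_xy = unname(touch_xy),
                 endpoint_planned_xy = unname(planned_xy),
                 corrected = corrected,
                 correction_start_s = corr_start_s),
            class = "reach_trial")
}

#' @export
print.reach_trial <- function(x, ...) {
  cat(sprintf("reach_trial %d (participant %s, experiment %d): %s %s -> %s\n",
              x$trial_id, as.character(x$participant_id), x$experiment,
              x$condition, x$initial_id, x$final_id))
  cat(sprintf("  %d samples at %.0f Hz; onset %.2f s, touch %.2f s%s\n",
              length(x$t), 1 / diff(x$t[1:2]),
              x$events$movement_onset_s, x$events$touch_s,
              if (isFALSE(x$corrected)) "; NOT corrected" else ""))
  invisible(x)
}

#' Simulate a full double-step reaching session
#'
#' Generates a randomized session for one participant: `n_static` static
#' trials balanced across the four static targets and `n_shifted` shifted
#' trials balanced across the four static parents, each parent's share split
#' as evenly as possible between its two shifted children (when the per-parent
#' count is odd, the extra trial goes to alternating children across parents,
#' deterministically). Presentation order is randomized through R's RNG; with
#' the defaults a session holds 120 trials, 60 static and 60 shifted.
#'
#' @param params A [sim_params()] (see [experiment_params()]).
#' @param layout A [target_layout()].
#' @param n_static,n_shifted Trial counts; each must be a positive multiple
#'   of 4 (the balanced design across static parents).
#' @param experiment,participant_id Labels stored on the session and trials.
#' @return An object of class `reach_session`: a list with `participant_id`,
#'   `experiment`, `trials` (list of [simulate_trial()] results in
#'   presentation order), `layout`, `params`.
#' @examples
#' set.seed(7)
#' sess <- simulate_session(experiment_params(1), target_layout(),
#'                          n_static = 8, n_shifted = 8)
#' length(sess$trials)
#' @export
simulate_session <- function(params, layout = target_layout(),
                             n_static = 60, n_shifted = 60,
                             experiment = 1L, participant_id = 1L) {
  stopifnot(inherits(params, "sim_params"), inherits(layout, "target_layout"))
  if (n_static <= 0 || n_static %% 4 != 0)
    stop("'n_static' must be a positive multiple of 4 ",
         "(balanced across the 4 static targets)")
  if (n_shifted <= 0 || n_shifted %% 4 != 0)
    stop("'n_shifted' must be a positive multiple of 4 ",
         "(balanced across the 4 static parents)")

  statics <- rownames(layout$static_targets)
  plan <- data.frame(condition = character(0), initial = character(0),
                     final = character(0), stringsAsFactors = FALSE)
  for (id in statics)
    plan <- rbind(plan, data.frame(condition = "static", initial = id,
                                   final = id,
                                   stringsAsFactors = FALSE)[rep(1, n_static / 4), ])
  per_parent <- n_shifted / 4
  for (i in seq_along(statics)) {
    id <- statics[i]
    children <- names(layout$parent)[layout$parent == id]
    n1 <- floor(per_parent / 2)
    n2 <- per_parent - n1
    # odd shares: the extra trial alternates between children across parents
    counts <- if (i %% 2 == 1) c(n2, n1) else c(n1, n2)
    for (j in 1:2) if (counts[j] > 0)
      plan <- rbind(plan, data.frame(condition = "shifted", initial = id,
                                     final = children[j],
                                     stringsAsFactors = FALSE)[rep(1, counts[j]), ])
  }
  ord <- sample.int(nrow(plan))
  plan <- plan[ord, ]

  trials <- vector("list", nrow(plan))
  for (k in seq_len(nrow(plan))) {
    trials[[k]] <- simulate_trial(layout, params,
                                  condition = plan$condition[k],
                                  initial_id = plan$initial[k],
                                  final_id = plan$final[k],
                                  experiment = experiment,
                                  participant_id = participant_id,
                                  trial_id = k)
  }
  structure(list(participant_id = participant_id,
                 experiment = as.integer(experiment),
                 trials = trials,
                 layout = layout,
                 params = params),
            class = "reach_session")
}

#' @export
print.reach_session <- function(x, ...) {
  cond <- vapply(x$trials, `[[`, "", "condition")
  cat(sprintf("reach_session: participant %s, experiment %d, %d trials (%d static / %d shifted)\n",
              as.character(x$participant_id), x$experiment, length(x$trials),
              sum(cond == "static"), sum(cond == "shifted")))
  invisible(x)
}

#' @export
summary.reach_session <- function(object, ...) {
  df <- session_table(object)
  agg <- stats::aggregate(duration_s ~ condition + dimension, df, mean)
  names(agg)[3] <- "mean_duration_s"
  agg$n <- stats::aggregate(duration_s ~ condition + dimension, df, length)$duration_s
  cat(sprintf("Session summary (participant %s, experiment %d)\n",
              as.character(object$participant_id), object$experiment))
  print(agg, row.names = FALSE)
  invisible(agg)
}

# One row per trial with labels, events and derived scalars.
session_table <- function(session) {
  do.call(rbind, lapply(session$trials, function(tr) {
    data.frame(trial_id = tr$trial_id,
               participant = as.character(tr$participant_id),
               experiment = tr$experiment,
               dimension = tr$dimension,
               condition = tr$condition,
               initial_id = tr$initial_id,
               final_id = tr$final_id,
               onset_s = tr$events$movement_onset_s,
               touch_s = tr$events$touch_s,
               duration_s = tr$events$touch_s - tr$events$movement_onset_s,
               corrected = tr$corrected,
               stringsAsFactors = FALSE)
  }))
}
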