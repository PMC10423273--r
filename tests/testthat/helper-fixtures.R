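# Shared fixtures: all data is generated in code, no files on disk.

# Minimal hand-built trial with prescribed coordinate series; both markers
# share the same path unless wrist series are given.
make_fake_trial <- function(t, x = 0 * t, y = 0 * t, z = 0 * t,
                            onset = t[1], touch = t[length(t)], cue = 0,
                            shift = NA_real_, condition = "static",
                            dimension = "horizontal", initial = "right",
                            final = initial, wrist = NULL) {
  xyz <- cbind(x = x, y = y, z = z)
  structure(list(trial_id = 1L, participant_id = 1L, experiment = 1L,
                 dimension = dimension, condition = condition,
                 initial_id = initial, final_id = final,
                 t = t, index_xyz = xyz,
                 wrist_xyz = if (is.null(wrist)) xyz else wrist,
                 events = list(cue_on_s = cue, movement_onset_s = onset,
                               shift_s = shift, touch_s = touch),
                 endpoint_touch_xy = unname(xyz[nrow(xyz), 1:2]),
                 endpoint_planned_xy = unname(xyz[nrow(xyz), 1:2]),
                 corrected = NA, correction_start_s = NA_real_),
            class = "reach_trial")
}

# Noise-free simulator settings (deterministic timing as well).
noisefree_params <- function(experiment = 1, ...) {
  defaults <- list(movement_duration_sd_ms = 0, reaction_time_sd_ms = 0,
                   correction_latency_horizontal_ms = c(195, 0),
                   correction_latency_sagittal_ms = c(290, 0),
                   position_noise_sd_cm = 0, endpoint_sd_cm = 0,
                   start_jitter_sd_cm = 0)
  do.call(experiment_params,
          c(list(experiment), utils::modifyList(defaults, list(...))))
}

# Small-network settings that keep GRU-based tests fast.
tiny_gru <- list(units = 16, epochs = 60, patience = 15)
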