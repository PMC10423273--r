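test_that("movement_segment uses inclusive bounds on the sample grid", {
  t <- seq(0, 1.2, by = 0.01)
  tr <- make_fake_trial(t, x = t, onset = 0.35, touch = 0.98)
  seg <- movement_segment(tr)
  expect_equal(length(seg$t), 64)  # 10 ms steps in [0.35, 0.98]
  expect_equal(seg$t[1], 0.35)
  # onset at the very first stamp
  tr0 <- make_fake_trial(t, onset = 0, touch = 0.5)
  expect_equal(movement_segment(tr0)$t[1], 0)
  # malformed trials
  tr_bad <- make_fake_trial(t, onset = 0.35, touch = 0.98)
  tr_bad$events$touch_s <- NA_real_
  expect_error(movement_segment(tr_bad), "missing")
  tr_rev <- make_fake_trial(t, onset = 0.9, touch = 0.5)
  expect_error(movement_segment(tr_rev), "touch at or before")
})

test_that("lateral velocity is an accurate central-difference derivative", {
  t <- seq(0, 1, by = 0.01)
  lin <- lateral_velocity(make_fake_trial(t, x = 2 * t))
  expect_equal(lin$v_lat[2:(length(t) - 1)], rep(2, length(t) - 2),
               tolerance = 1e-9)
  flat <- lateral_velocity(make_fake_trial(t, x = rep(1, length(t))))
  expect_equal(flat$v_lat, rep(0, length(t)), tolerance = 1e-12)
  sine <- lateral_velocity(make_fake_trial(t, x = sin(2 * pi * t)))
  truth <- 2 * pi * cos(2 * pi * t)
  expect_lt(max(abs(sine$v_lat - truth)[2:(length(t) - 1)]), 0.05)
  expect_error(lateral_velocity(make_fake_trial(t[1:2], x = t[1:2])),
               "at least 3|too short")
})

test_that("deviation detection finds a deterministic step and is symmetric", {
  set.seed(11)
  n <- 30; p <- 60
  base <- matrix(rnorm(n * p, 0, 0.01), n, p)
  a <- base
  b <- matrix(rnorm(n * p, 0, 0.01), n, p)
  b[, 21:p] <- b[, 21:p] + 5  # step at sample index 20 (0-based)
  t_ms <- (0:(p - 1)) * 10
  dev <- detect_deviation_time(a, b, t_ms = t_ms)
  expect_equal(dev$deviation_time_ms, 200, tolerance = 10)
  dev_swap <- detect_deviation_time(b, a, t_ms = t_ms)
  expect_equal(dev$deviation_time_ms, dev_swap$deviation_time_ms)
  expect_equal(dev$p, dev_swap$p)
  # identical groups: nothing to detect
  none <- detect_deviation_time(a, a + 0)
  expect_true(is.na(none$deviation_time_ms))
})

test_that("no corrections are detectable for sagittal shifts in experiment 2", {
  lay <- target_layout()
  par <- experiment_params(2)
  absent <- vapply(1:10, function(s) {
    set.seed(500 + s)
    near <- lapply(1:30, function(i)
      simulate_trial(lay, par, "shifted", "near", "near_n"))
    far <- lapply(1:30, function(i)
      simulate_trial(lay, par, "shifted", "near", "near_f"))
    is.na(detect_deviation_time(velocity_traces(near, smooth_window = 5),
                                velocity_traces(far, smooth_window = 5))$deviation_time_ms)
  }, logical(1))
  expect_gte(sum(absent), 9)
})

test_that("endpoint error is the planar Euclidean distance", {
  expect_equal(endpoint_error(c(3, 4), c(0, 0)), 5)
  expect_equal(endpoint_error(c(1.2, -0.7), c(1.2, -0.7)), 0)
  expect_error(endpoint_error(c(NA, 1), c(0, 0)), "finite")
  # triangle inequality against arbitrary intermediate points
  set.seed(12)
  for (i in 1:50) {
    a <- rnorm(2); b <- rnorm(2); m <- rnorm(2)
    expect_lte(endpoint_error(a, b),
               endpoint_error(a, m) + endpoint_error(m, b) + 1e-12)
  }
})

test_that("uncorrected shifted trials have larger mean endpoint error", {
  set.seed(13)
  lay <- target_layout()
  corr <- replicate(40, {
    tr <- simulate_trial(lay, experiment_params(1), "shifted", "near", "near_f")
    endpoint_error(tr$endpoint_touch_xy, lay$shifted_targets["near_f", ])
  })
  uncorr <- replicate(40, {
    tr <- simulate_trial(lay, experiment_params(2), "shifted", "near", "near_f")
    endpoint_error(tr$endpoint_touch_xy, lay$shifted_targets["near_f", ])
  })
  expect_gt(mean(uncorr), mean(corr))
})

test_that("reaction times are cue-to-onset intervals", {
  t <- seq(0, 2.5, by = 0.01)
  tr <- make_fake_trial(t, onset = 1.85, touch = 2.5, cue = 1.5)
  expect_equal(reaction_time(tr), 350)
  tr_bad <- make_fake_trial(t, onset = 1.0, touch = 2.0, cue = 1.5)
  expect_error(reaction_time(tr_bad), "before cue")
  # simulated sessions track the configured mean
  set.seed(14)
  sess <- simulate_session(experiment_params(1), n_static = 20, n_shifted = 20)
  rts <- vapply(sess$trials, reaction_time, numeric(1))
  expect_lt(abs(mean(rts) - 350), 3 * 50 / sqrt(40) + 5)
})

test_that("peak-velocity variability measures across-trial spread", {
  t <- seq(0, 1, by = 0.01)
  path <- minimum_jerk(c(0, 0, 0), c(0, 10, 0), 1, length(t))
  mk <- function(dx) make_fake_trial(t, x = path[, 1] + dx, y = path[, 2],
                                     z = path[, 3])
  expect_equal(peak_velocity_variability(list(mk(0), mk(0), mk(0)), "x"), 0)
  expect_equal(peak_velocity_variability(list(mk(1), mk(3)), "x"), sqrt(2))
  expect_error(peak_velocity_variability(list(mk(1)), "x"), "at least 2")
  # static reaches with default noise stay tight at peak velocity
  set.seed(15)
  lay <- target_layout()
  trials <- lapply(1:20, function(i)
    simulate_trial(lay, experiment_params(1, start_jitter_sd_cm = 0),
                   "static", "far"))
  expect_lt(peak_velocity_variability(trials, "x"), 0.4)
})

test_that("movement summaries aggregate durations and speeds", {
  t <- seq(0, 0.63, by = 0.01)
  tr <- make_fake_trial(t, x = t)
  ms <- movement_summary(list(tr))
  expect_equal(ms$by_condition$mean_duration_s, 0.63)
  # identical duration sets across experiments: no corrected difference
  set.seed(16)
  d1 <- rnorm(12, 0.63, 0.05); d2 <- d1
  res <- corrected_two_sample_test(d1, d2, alpha = 0.05, n_comparisons = 4)
  expect_false(res$significant)
  expect_gt(res$p_value, 0.99)
})
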