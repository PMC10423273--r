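test_that("default sessions have the task's trial structure", {
  set.seed(101)
  sess <- simulate_session(experiment_params(1))
  expect_s3_class(sess, "reach_session")
  expect_length(sess$trials, 120)
  cond <- vapply(sess$trials, `[[`, "", "condition")
  expect_equal(sum(cond == "static"), 60)
  expect_equal(sum(cond == "shifted"), 60)
  # balance: 15 static per target, 15 shifted per parent
  finals <- vapply(sess$trials, `[[`, "", "final_id")
  expect_equal(unname(table(finals[cond == "static"])), rep(15L, 4),
               ignore_attr = TRUE)
  parents <- sess$layout$parent[finals[cond == "shifted"]]
  expect_equal(unname(table(parents)), rep(15L, 4), ignore_attr = TRUE)
})

test_that("trial time base and events satisfy the data-model invariants", {
  set.seed(102)
  sess <- simulate_session(experiment_params(2), n_static = 8, n_shifted = 8)
  for (tr in sess$trials) {
    dt <- diff(tr$t)
    expect_true(all(dt > 0))
    expect_equal(max(abs(dt - 0.01)), 0, tolerance = 1e-9)
    expect_lt(tr$events$movement_onset_s, tr$events$touch_s)
    expect_equal(nrow(tr$index_xyz), length(tr$t))
    expect_equal(nrow(tr$wrist_xyz), length(tr$t))
    if (tr$condition == "shifted") {
      expect_gte(tr$events$shift_s, tr$events$movement_onset_s)
      expect_equal(unname(sess$layout$parent[tr$final_id]), tr$initial_id)
    } else {
      expect_identical(tr$initial_id, tr$final_id)
    }
  }
})

test_that("sessions are bitwise reproducible under a seed", {
  set.seed(7); s1 <- simulate_session(experiment_params(1), n_static = 8, n_shifted = 8)
  set.seed(7); s2 <- simulate_session(experiment_params(1), n_static = 8, n_shifted = 8)
  expect_identical(s1, s2)
  set.seed(8); s3 <- simulate_session(experiment_params(1), n_static = 8, n_shifted = 8)
  expect_false(identical(s1$trials[[1]]$index_xyz, s3$trials[[1]]$index_xyz))
})

test_that("noise-free trials land exactly on their target", {
  lay <- target_layout()
  set.seed(1)
  tr <- simulate_trial(lay, noisefree_params(), "static", "right")
  expect_equal(tr$endpoint_touch_xy, unname(lay$static_targets["right", ]),
               tolerance = 1e-9)
  # corrected shifted trial: planned endpoint on the final (shifted) target
  ts <- simulate_trial(lay, noisefree_params(), "shifted", "left", "left_r")
  expect_true(ts$corrected)
  expect_equal(ts$endpoint_planned_xy,
               unname(lay$shifted_targets["left_r", ]), tolerance = 1e-9)
})

test_that("planned endpoints lie on the labeled target under default noise", {
  set.seed(103)
  sess <- simulate_session(experiment_params(1), n_static = 8, n_shifted = 8)
  for (tr in sess$trials) {
    if (isFALSE(tr$corrected)) next
    expect_equal(tr$endpoint_planned_xy,
                 unname(endpoint_position(sess$layout, tr$final_id)),
                 tolerance = 1e-9)
  }
})

test_that("uncorrected sagittal trials miss by about the shift distance", {
  lay <- target_layout()
  set.seed(2)
  par <- noisefree_params(2)  # p_no_correction_sagittal = 1
  tr <- simulate_trial(lay, par, "shifted", "near", "near_f")
  expect_false(tr$corrected)
  expect_equal(endpoint_error(tr$endpoint_touch_xy,
                              lay$shifted_targets["near_f", ]),
               2.4, tolerance = 1e-9)
})

test_that("an injected 195 ms latency shows up in the lateral velocity", {
  lay <- target_layout()
  par <- noisefree_params()
  set.seed(3)
  shifted <- simulate_trial(lay, par, "shifted", "left", "left_r")
  static <- simulate_trial(lay, par, "static", "left")
  vs <- lateral_velocity(shifted)  # aligned to shift
  vt <- lateral_velocity(static)   # aligned to onset; shift at onset here
  common <- intersect(round(vs$t_rel_ms), round(vt$t_rel_ms))
  dv <- abs(vs$v_lat[match(common, round(vs$t_rel_ms))] -
              vt$v_lat[match(common, round(vt$t_rel_ms))])
  depart <- common[which(dv > 0.5)[1]]
  expect_gte(depart, 180)
  expect_lte(depart, 220)
})

test_that("correction latencies past touch are flagged as uncorrected", {
  lay <- target_layout()
  set.seed(4)
  par <- noisefree_params(correction_latency_horizontal_ms = c(5000, 0))
  tr <- simulate_trial(lay, par, "shifted", "right", "right_l")
  expect_false(tr$corrected)
  expect_equal(endpoint_error(tr$endpoint_touch_xy,
                              lay$shifted_targets["right_l", ]),
               2.4, tolerance = 1e-9)
})

test_that("movement durations match the intended distribution", {
  set.seed(105)
  lay <- target_layout()
  par <- experiment_params(1)
  dur <- replicate(200, {
    tr <- simulate_trial(lay, par, "static", "far")
    (tr$events$touch_s - tr$events$movement_onset_s) * 1000
  })
  # mean ~630 ms (3 standard errors of the truncated-normal draw)
  expect_lt(abs(mean(dur) - 630), 3 * 60 / sqrt(200) + 5)
  expect_gte(min(dur), 400)
})

test_that("session and trial constructors reject inconsistent requests", {
  lay <- target_layout()
  par <- sim_params()
  expect_error(simulate_session(par, lay, n_static = 10), "multiple of 4")
  expect_error(simulate_session(par, lay, n_shifted = 6), "multiple of 4")
  expect_error(simulate_trial(lay, par, "static", "right", "left"),
               "final_id == initial_id")
  expect_error(simulate_trial(lay, par, "shifted", "right", "left_l"),
               "shifted child")
  expect_error(simulate_trial(lay, par, "shifted", "left_l", "left_l"),
               "static endpoint")
})

test_that("minimal balanced sessions cover each endpoint once", {
  set.seed(106)
  sess <- simulate_session(sim_params(), n_static = 4, n_shifted = 8)
  expect_length(sess$trials, 12)
  finals <- sort(vapply(sess$trials, `[[`, "", "final_id"))
  lay <- sess$layout
  expect_equal(finals, sort(c(rownames(lay$static_targets),
                              rownames(lay$shifted_targets))))
})
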