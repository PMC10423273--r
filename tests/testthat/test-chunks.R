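test_that("trials normalize to 100 samples with linear interpolation", {
  set.seed(21)
  sess <- simulate_session(experiment_params(1), n_static = 4, n_shifted = 4)
  nt <- normalize_trial(sess$trials[[1]])
  expect_equal(dim(nt), c(100, 6))
  expect_true(all(is.finite(nt)))

  # constant series stay constant; a linear ramp maps to i/99
  t <- seq(0, 0.99, by = 0.01)
  ramp <- seq(0, 1, length.out = length(t))
  tr <- make_fake_trial(t, x = ramp, y = rep(2, length(t)))
  nt2 <- normalize_trial(tr)
  expect_equal(nt2[, "ix"], (0:99) / 99, tolerance = 1e-9)
  expect_equal(nt2[, "iy"], rep(2, 100))
})

test_that("chunk extraction yields the documented counts and end indices", {
  m <- matrix(rnorm(600), 100, 6)
  c4 <- extract_chunks(m, chunk_len = 8, stride = 4)
  expect_length(c4$chunks, 24)
  c1 <- extract_chunks(m, chunk_len = 8, stride = 1)
  expect_length(c1$chunks, 93)
  expect_equal(c1$end_index, 7:99)
  cw <- extract_chunks(m, chunk_len = 100, stride = 1)
  expect_length(cw$chunks, 1)
  expect_equal(cw$end_index, 99)
  expect_true(all(vapply(c4$chunks, nrow, 0L) == 8))
  expect_error(extract_chunks(m, chunk_len = 101), "exceeds")
  expect_error(extract_chunks(m, stride = 0), "stride")
})

test_that("goal datasets label every chunk with the trial's final endpoint", {
  set.seed(22)
  sess <- simulate_session(experiment_params(1))
  prob <- decoding_problem(sess, "horizontal", "static")
  expect_setequal(prob$classes, c("left", "right"))
  expect_true(all(vapply(prob$trials, `[[`, "", "condition") == "static"))
  d <- build_goal_dataset(prob)
  expect_equal(dim(d$x), c(24 * length(prob$trials), 8, 6))
  expect_equal(nlevels(d$y), 2)
  # chunk labels match their source trial's label
  for (i in sample(length(d$trial), 20))
    expect_equal(as.character(d$y[i]),
                 prob$trials[[d$trial[i]]]$final_id)
  # pre-movement window: 50 raw samples -> 11 chunks per trial at stride 4
  dp <- build_goal_dataset(prob, window = "pre_movement")
  expect_equal(dim(dp$x)[1], 11 * length(prob$trials))
})

test_that("shifted-pair and six-way problems select the right endpoints", {
  set.seed(23)
  sess <- simulate_session(experiment_params(1))
  pl <- decoding_problem(sess, "horizontal", "shifted_left")
  expect_setequal(pl$classes, c("left_l", "left_r"))
  expect_true(all(vapply(pl$trials, `[[`, "", "condition") == "shifted"))
  p6 <- decoding_problem(sess, "sagittal", "sixway")
  expect_length(p6$classes, 6)
  expect_error(decoding_problem(sess, "sagittal", "shifted_left"),
               "not defined")
})

test_that("chance level is the reciprocal of the class count", {
  expect_equal(chance_level(2), 0.5)
  expect_equal(chance_level(6), 1 / 6)
  expect_lt(abs(chance_level(6) - 0.16), 0.01)
  expect_error(chance_level(1), ">= 2")
})

test_that("stratified folds split 60 balanced trials into 48 train / 12 test", {
  set.seed(24)
  labels <- rep(c("a", "b"), each = 30)
  fold <- stratified_folds(labels, 5)
  for (f in 1:5) {
    expect_equal(sum(fold == f), 12)
    expect_equal(sum(fold == f & labels == "a"), 6)
  }
  expect_setequal(unique(fold), 1:5)
  expect_error(stratified_folds(rep(c("a", "b"), c(3, 30)), 5),
               "fewer trials than folds")
  # reproducible under seed
  set.seed(24); f1 <- stratified_folds(labels, 5)
  set.seed(24); f2 <- stratified_folds(labels, 5)
  expect_identical(f1, f2)
})
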