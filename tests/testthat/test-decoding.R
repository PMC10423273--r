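test_that("accuracy curves have unit-stride resolution and exact bounds", {
  set.seed(41)
  sess <- simulate_session(experiment_params(1), n_static = 8, n_shifted = 8)
  prob <- decoding_problem(sess, "horizontal", "static")
  d1 <- build_goal_dataset(prob, stride = 1)
  # a perfect oracle model gives accuracy 1 everywhere
  oracle <- function(x) as.character(d1$y)
  curve <- evaluate_accuracy_curve(oracle, d1)
  expect_equal(nrow(curve), 93)
  expect_true(all(curve$accuracy == 1))
  # a constant model scores the class frequency on a balanced set
  const <- function(x) rep(levels(d1$y)[1], dim(x)[1])
  curve0 <- evaluate_accuracy_curve(const, d1)
  expect_true(all(curve0$accuracy == mean(d1$y == levels(d1$y)[1])))
})

test_that("cross-validated goal decoding separates static targets and is leak-free", {
  set.seed(42)
  sess <- simulate_session(experiment_params(1))
  gd <- do.call(decode_goals, c(list(sess, "horizontal", "static", seed = 5),
                                tiny_gru))
  expect_s3_class(gd, "goal_decoding")
  expect_equal(nrow(gd$curve), 93)
  expect_equal(gd$curve$pct_movement, (7:99) / 99 * 100)
  expect_true(all(gd$curve$accuracy >= 0 & gd$curve$accuracy <= 1))
  # fold-averaged curve is the pointwise mean of fold curves
  expect_equal(gd$curve$accuracy, colMeans(gd$fold_curves))
  # folds partition the trials: no train/test leakage is possible
  expect_equal(sort(unique(gd$fold)), 1:5)
  expect_length(gd$fold, gd$n_trials)
  for (f in 1:5)
    expect_equal(sum(gd$fold == f), gd$n_trials / 5)
  # strong separation late in the movement
  expect_gte(max(gd$curve$accuracy), 0.9)
  # same seed reproduces the analysis exactly
  gd2 <- do.call(decode_goals, c(list(sess, "horizontal", "static", seed = 5),
                                 tiny_gru))
  expect_identical(gd$curve, gd2$curve)
})

test_that("static goals become decodable earlier than shifted goals", {
  set.seed(43)
  sess <- simulate_session(experiment_params(1))
  gd_static <- do.call(decode_goals,
                       c(list(sess, "horizontal", "static", seed = 6), tiny_gru))
  gd_shift <- do.call(decode_goals,
                      c(list(sess, "horizontal", "shifted_left", seed = 6),
                        tiny_gru))
  first_near_max <- function(gd) {
    acc <- gd$curve$accuracy
    gd$curve$end_index[which(acc >= 0.95 * max(acc))[1]]
  }
  expect_lt(first_near_max(gd_static), first_near_max(gd_shift))
})

test_that("the training-label permutation null sits at chance", {
  set.seed(48)
  sess <- simulate_session(experiment_params(1))
  accs <- vapply(1:3, function(p) {
    gd <- decode_goals(sess, "horizontal", "static", permute_labels = TRUE,
                       units = 8, epochs = 30, patience = 10, seed = 48 + p)
    mean(gd$fold_curves)
  }, numeric(1))
  expect_gte(mean(accs), 0.35)
  expect_lte(mean(accs), 0.65)
})

test_that("per-window training mode evaluates at the training window grid", {
  set.seed(44)
  sess <- simulate_session(experiment_params(1), n_static = 24, n_shifted = 8)
  gd <- decode_goals(sess, "horizontal", "static", mode = "per_window",
                     folds = 3, units = 6, epochs = 15, patience = 5, seed = 7)
  expect_equal(nrow(gd$curve), 24)
  expect_true(all(gd$curve$accuracy >= 0 & gd$curve$accuracy <= 1))
})

test_that("regression datasets drop chunks whose future falls outside the trial", {
  set.seed(45)
  sess <- simulate_session(experiment_params(1), n_static = 8, n_shifted = 8)
  trials <- cluster_trials(sess, "left")
  d4 <- build_regression_dataset(trials, offset = 4)
  expect_equal(sum(d4$trial == 1), 23)   # end_index + 4 <= 99
  d30 <- build_regression_dataset(trials, offset = 30)
  expect_equal(sum(d30$trial == 1), 16)  # end_index + 30 <= 99
  # targets are the trial's own future feature values
  nt <- normalize_trial(trials[[1]])
  i <- which(d4$trial == 1)[3]
  expect_equal(d4$y[i, ], nt[d4$end_index[i] + 4 + 1, ])
  expect_error(build_regression_dataset(trials, offset = 99), "no valid chunks")
})

test_that("R-squared scoring matches its closed-form cases", {
  set.seed(46)
  sess <- simulate_session(experiment_params(1), n_static = 8, n_shifted = 8)
  d <- build_regression_dataset(cluster_trials(sess, "right"), offset = 8)
  ident <- function(x) d$y
  expect_equal(unname(evaluate_r2(ident, d)), rep(1, 6))
  meanm <- function(x) matrix(colMeans(d$y), nrow(d$y), 6, byrow = TRUE)
  expect_equal(unname(evaluate_r2(meanm, d)), rep(0, 6), tolerance = 1e-12)
})

test_that("near-future positions are predictable on smooth simulated reaches", {
  set.seed(47)
  sess <- simulate_session(experiment_params(1))
  hyper <- utils::modifyList(tiny_gru, list(epochs = 100))
  td <- do.call(decode_trajectory,
                c(list(sess, "left", offsets = 8, seed = 8), hyper))
  expect_s3_class(td, "trajectory_decoding")
  expect_true(all(td$r2 <= 1))
  expect_gte(mean(td$r2_index), 0.7)
})
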