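#' Configuration for an end-to-end double-step experiment run
#'
#' Bundles every parameter of [run_experiment()] with validated defaults.
#' The defaults are a desk-scale smoke configuration (2 participants per
#' experiment, small network, reduced epochs); a paper-scale run uses 12
#' participants in Experiment 1, 11 in Experiment 2, 100 GRU units and long
#' training (`epochs = 10000, patience = 500`).
#'
#' @param seed Global seed; per-stage seeds are derived as
#'   `seed + 1000 * stage_index` (stage 1 simulation, 2 kinematics,
#'   3 decoding, 4 statistics), so stages are independently reproducible.
#' @param n_participants Named integer vector: participants per experiment.
#' @param n_static,n_shifted Trials per session.
#' @param dimensions Dimensions to analyse.
#' @param problems Goal-decoding problems run per dimension (shifted problems
#'   incompatible with a dimension are skipped automatically).
#' @param offsets Regression offsets; `NULL` disables trajectory regression.
#' @param clusters Target clusters for the regression stage.
#' @param units,epochs,patience GRU hyperparameters.
#' @param alpha,n_perm,crossing_run_length,deviation_run_length Statistics
#'   settings.
#' @param velocity_smooth_window Centred moving-average width (samples)
#'   applied to lateral velocity before deviation-time testing; finite
#'   differencing amplifies marker noise, and 50 ms of smoothing suppresses
#'   it while staying far below the latency differences of interest.
#' @param out_dir Optional output directory: resolved config, result tables
#'   and a log are written there.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(seed = 1,
                       n_participants = c("1" = 2, "2" = 2),
                       n_static = 60, n_shifted = 60,
                       dimensions = "horizontal",
                       problems = c("static", "shifted_left", "shifted_right",
                                    "shifted_near", "shifted_far"),
                       offsets = 8,
                       clusters = "left",
                       units = 16, epochs = 60, patience = 15,
                       alpha = 0.05, n_perm = 200,
                       crossing_run_length = 3, deviation_run_length = 10,
                       velocity_smooth_window = 5,
                       out_dir = NULL) {
  cfg <- list(seed = as.integer(seed), n_participants = n_participants,
              n_static = n_static, n_shifted = n_shifted,
              dimensions = dimensions, problems = problems,
              offsets = offsets, clusters = clusters,
              units = units, epochs = epochs, patience = patience,
              alpha = alpha, n_perm = n_perm,
              crossing_run_length = crossing_run_length,
              deviation_run_length = deviation_run_length,
              velocity_smooth_window = velocity_smooth_window,
              out_dir = out_dir)
  stopifnot(all(names(cfg$n_participants) %in% c("1", "2")),
            all(cfg$n_participants >= 1),
            all(cfg$dimensions %in% c("horizontal", "sagittal")),
            cfg$alpha > 0, cfg$alpha < 1, cfg$n_perm >= 10)
  structure(cfg, class = "run_config")
}

# Stable content hash (polynomial rolling hash over the serialized object)
# for provenance tagging of report tables.
config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 0
  for (b in as.integer(raw)) h <- (h * 31 + b) %% 1000000007
  sprintf("%08x", h)
}

#' Run the full simulated double-step analysis pipeline
#'
#' Simulates sessions for each experiment, then runs the kinematic stage
#' (lateral-velocity deviation times per dimension, endpoint errors, reaction
#' times, peak-velocity variability), the decoding stage (cross-validated
#' goal decoding per participant and problem; optional future-trajectory
#' regression), and the statistics stage (static-vs-shifted curve
#' comparisons, chance-crossing times, confidence ellipses over per
#' -participant crossing times when both dimensions are analysed, KS test on
#' R-squared between experiments). Everything is deterministic under the
#' config seed. If `out_dir` is set, result tables, the resolved config and a
#' log are written there.
#'
#' @param config A [run_config()].
#' @return An object of class `experiment_report` (a list of result tables;
#'   see [run_config()] for the stages).
#' @export
run_experiment <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), msg))
    message(msg)
  }
  stage_seed <- function(i) config$seed + 1000L * i

  # stage 1: simulation
  say("stage 1: simulating sessions")
  sessions <- list()
  for (exp in names(config$n_participants)) {
    exp_i <- as.integer(exp)
    sessions[[exp]] <- lapply(seq_len(config$n_participants[[exp]]), function(p) {
      set.seed(stage_seed(1L) + 100L * exp_i + p)
      simulate_session(experiment_params(exp_i), target_layout(),
                       n_static = config$n_static,
                       n_shifted = config$n_shifted,
                       experiment = exp_i, participant_id = p)
    })
  }

  # stage 2: kinematics
  say("stage 2: kinematic analyses")
  set.seed(stage_seed(2L))
  deviation <- list(); endpoint <- list(); rts <- list()
  for (exp in names(sessions)) {
    all_trials <- do.call(c, lapply(sessions[[exp]], `[[`, "trials"))
    for (dim in config$dimensions) {
      shifted <- Filter(function(tr) tr$condition == "shifted" &&
                          tr$dimension == dim, all_trials)
      children <- sort(unique(vapply(shifted, `[[`, "", "final_id")))
      by_child <- split(shifted, vapply(shifted, `[[`, "", "final_id"))
      # compare the two corrective directions within each static parent
      parents <- unique(sub("_[lrnf]$", "", children))
      for (par in parents) {
        kids <- grep(paste0("^", par, "_"), children, value = TRUE)
        if (length(kids) != 2) next
        w <- config$velocity_smooth_window
        dev <- detect_deviation_time(
          velocity_traces(by_child[[kids[1]]], smooth_window = w),
          velocity_traces(by_child[[kids[2]]], smooth_window = w),
          alpha = config$alpha,
          run_length = config$deviation_run_length)
        deviation[[length(deviation) + 1]] <-
          data.frame(experiment = as.integer(exp), dimension = dim,
                     parent = par,
                     deviation_time_ms = dev$deviation_time_ms)
      }
    }
    lay <- sessions[[exp]][[1]]$layout
    err <- vapply(all_trials, function(tr)
      endpoint_error(tr$endpoint_touch_xy,
                     endpoint_position(lay, tr$final_id)), numeric(1))
    endpoint[[exp]] <- data.frame(
      experiment = as.integer(exp),
      dimension = vapply(all_trials, `[[`, "", "dimension"),
      condition = vapply(all_trials, `[[`, "", "condition"),
      error_cm = err)
    rts[[exp]] <- data.frame(
      experiment = as.integer(exp),
      condition = vapply(all_trials, `[[`, "", "condition"),
      rt_ms = vapply(all_trials, reaction_time, numeric(1)))
  }
  deviation <- do.call(rbind, deviation)
  endpoint_errors <- stats::aggregate(
    error_cm ~ experiment + dimension + condition,
    do.call(rbind, endpoint), mean)
  reaction_times <- stats::aggregate(rt_ms ~ experiment + condition,
                                     do.call(rbind, rts), mean)

  # stage 3: decoding
  say("stage 3: goal decoding (%d participants x problems)",
      sum(config$n_participants))
  curves <- list(); crossing <- list()
  for (exp in names(sessions)) {
    for (dim in config$dimensions) {
      probs <- intersect(config$problems, valid_problems(dim))
      for (prob in probs) {
        key <- paste(exp, dim, prob, sep = ".")
        mats <- list()
        for (p in seq_along(sessions[[exp]])) {
          gd <- decode_goals(sessions[[exp]][[p]], dim, prob,
                             units = config$units, epochs = config$epochs,
                             patience = config$patience,
                             seed = stage_seed(3L) + 100L * as.integer(exp) +
                               10L * p + match(prob, valid_problems(dim)))
          mats[[p]] <- gd$curve$accuracy
          crossing[[length(crossing) + 1]] <- data.frame(
            experiment = as.integer(exp), dimension = dim, problem = prob,
            participant = p,
            crossing_pct = chance_crossing_time(
              gd, level = gd$chance,
              run_length = config$crossing_run_length))
        }
        curves[[key]] <- do.call(rbind, mats)
      }
    }
  }
  crossing_times <- do.call(rbind, crossing)

  r2_tables <- NULL
  if (!is.null(config$offsets)) {
    say("stage 3b: trajectory regression")
    r2_rows <- list()
    for (exp in names(sessions)) {
      for (cl in config$clusters) {
        for (p in seq_along(sessions[[exp]])) {
          td <- decode_trajectory(sessions[[exp]][[p]], cl,
                                  offsets = config$offsets,
                                  units = config$units,
                                  epochs = config$epochs,
                                  patience = config$patience,
                                  seed = stage_seed(3L) + 5000L +
                                    100L * as.integer(exp) + 10L * p +
                                    match(cl, c("left", "right", "near", "far")))
          for (oi in seq_along(config$offsets))
            r2_rows[[length(r2_rows) + 1]] <- data.frame(
              experiment = as.integer(exp), cluster = cl, participant = p,
              offset = config$offsets[oi],
              component = c("x", "y", "z"),
              r2 = as.numeric(td$r2_index[oi, ]))
        }
      }
    }
    r2_tables <- do.call(rbind, r2_rows)
  }

  # stage 4: statistics
  say("stage 4: curve statistics")
  set.seed(stage_seed(4L))
  comparisons <- list()
  for (exp in names(sessions)) {
    for (dim in config$dimensions) {
      probs <- intersect(config$problems, valid_problems(dim))
      shifted_probs <- setdiff(probs, "static")
      if (!"static" %in% probs) next
      for (sp in shifted_probs) {
        a <- curves[[paste(exp, dim, "static", sep = ".")]]
        b <- curves[[paste(exp, dim, sp, sep = ".")]]
        if (is.null(a) || is.null(b) || nrow(a) < 2 || nrow(b) < 2) next
        cmp <- hotelling_curve_test(a, b, alpha = config$alpha,
                                    n_perm = config$n_perm)
        comparisons[[paste(exp, dim, "static_vs", sp, sep = ".")]] <- cmp
      }
    }
  }
  ellipses <- list()
  if (all(c("horizontal", "sagittal") %in% config$dimensions)) {
    for (exp in names(sessions)) {
      ct <- crossing_times[crossing_times$experiment == as.integer(exp) &
                             crossing_times$problem != "static", ]
      per_part <- stats::aggregate(crossing_pct ~ participant + dimension,
                                   ct, mean, na.action = stats::na.omit)
      wide <- stats::reshape(per_part, idvar = "participant",
                             timevar = "dimension", direction = "wide")
      pts <- wide[stats::complete.cases(wide), -1, drop = FALSE]
      ellipses[[exp]] <- if (nrow(pts) >= 3)
        confidence_ellipse(as.matrix(pts)) else NA
    }
  }
  ks_r2 <- NULL
  if (!is.null(r2_tables) && length(unique(r2_tables$experiment)) == 2) {
    ks_r2 <- compare_r2_distributions(
      r2_tables$r2[r2_tables$experiment == 1],
      r2_tables$r2[r2_tables$experiment == 2])
  }

  report <- structure(list(
    config = config,
    provenance = list(config_hash = config_hash(unclass(config)),
                      seed = config$seed,
                      package_version = as.character(utils::packageVersion("doublestep")),
                      r_version = R.version.string),
    deviation_times = deviation,
    endpoint_errors = endpoint_errors,
    reaction_times = reaction_times,
    curves = curves,
    crossing_times = crossing_times,
    comparisons = comparisons,
    ellipses = ellipses,
    r2 = r2_tables,
    ks_r2 = ks_r2,
    log = log_lines), class = "experiment_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

valid_problems <- function(dimension) {
  if (dimension == "horizontal")
    c("static", "shifted_left", "shifted_right", "sixway")
  else c("static", "shifted_near", "shifted_far", "sixway")
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) if (!is.null(df))
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  w(report$deviation_times, "deviation_times.csv")
  w(report$endpoint_errors, "endpoint_errors.csv")
  w(report$reaction_times, "reaction_times.csv")
  w(report$crossing_times, "crossing_times.csv")
  w(report$r2, "r2.csv")
  curve_rows <- do.call(rbind, lapply(names(report$curves), function(k) {
    m <- report$curves[[k]]
    data.frame(key = k, participant = rep(seq_len(nrow(m)), each = ncol(m)),
               node = rep(seq_len(ncol(m)), nrow(m)),
               accuracy = as.numeric(t(m)))
  }))
  w(curve_rows, "accuracy_curves.csv")
  cfg <- unclass(report$config)
  jsonlite::write_json(list(config = cfg,
                            provenance = report$provenance),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(report$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Double-step experiment report\n")
  cat(sprintf("  seed %d, config hash %s\n", x$provenance$seed,
              x$provenance$config_hash))
  cat(sprintf("  %d decoding curve sets, %d curve comparisons\n",
              length(x$curves), length(x$comparisons)))
  if (!is.null(x$deviation_times)) {
    cat("  deviation times (ms):\n")
    print(x$deviation_times, row.names = FALSE)
  }
  invisible(x)
}
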