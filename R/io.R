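SESSION_COLS <- c("trial_id", "participant", "experiment", "dimension",
                  "condition", "initial_id", "final_id", "t_s", "marker",
                  "x", "y", "z")

#' Write a session to disk (long CSV + JSON sidecar)
#'
#' The CSV holds one row per time stamp per marker (columns `trial_id,
#' participant, experiment, dimension, condition, initial_id, final_id, t_s,
#' marker, x, y, z`; positions in cm to 6 decimals). The JSON sidecar (same
#' path with extension `.json`) carries per-trial events and labels plus the
#' layout distances and simulation parameters, so [read_session()] restores a
#' complete `reach_session`.
#'
#' @param session A `reach_session`.
#' @param path CSV file path; the sidecar replaces the extension with
#'   `.json`.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "reach_session"))
  rows <- lapply(session$trials, function(tr) {
    n <- length(tr$t)
    base <- data.frame(trial_id = tr$trial_id,
                       participant = as.character(tr$participant_id),
                       experiment = tr$experiment,
                       dimension = tr$dimension,
                       condition = tr$condition,
                       initial_id = tr$initial_id,
                       final_id = tr$final_id,
                       stringsAsFactors = FALSE)
    rbind(cbind(base[rep(1, n), ], t_s = round(tr$t, 6), marker = "index",
                round(tr$index_xyz, 6)),
          cbind(base[rep(1, n), ], t_s = round(tr$t, 6), marker = "wrist",
                round(tr$wrist_xyz, 6)))
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE)

  side <- list(
    participant_id = as.character(session$participant_id),
    experiment = session$experiment,
    layout = list(static_distance = session$layout$static_distance,
                  shift_distance = session$layout$shift_distance),
    params = unclass(session$params),
    trials = lapply(session$trials, function(tr) {
      list(trial_id = tr$trial_id,
           events = tr$events,
           endpoint_touch_xy = tr$endpoint_touch_xy,
           endpoint_planned_xy = tr$endpoint_planned_xy,
           corrected = tr$corrected,
           correction_start_s = tr$correction_start_s)
    }))
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)

#' Read a session written by [write_session()]
#'
#' Validates the CSV schema (required columns, uniform 100 Hz-style time base
#' per trial, matching index/wrist lengths) and reconstructs the
#' `reach_session`, including events and labels from the JSON sidecar.
#' Positions round-trip to the CSV's 6-decimal precision.
#'
#' @param path CSV file path (sidecar expected alongside).
#' @return A `reach_session`.
#' @export
read_session <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(SESSION_COLS, names(df))
  if (length(missing_cols))
    stop("session file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  side_path <- sidecar_path(path)
  if (!file.exists(side_path)) stop("missing JSON sidecar: ", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = FALSE)

  num_or_na <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  params <- do.call(sim_params, lapply(side$params, function(v) unlist(v)))
  layout <- target_layout(side$layout$static_distance,
                          side$layout$shift_distance)

  meta_ids <- vapply(side$trials, function(m) as.integer(m$trial_id), 0L)
  trial_ids <- sort(unique(df$trial_id))
  trials <- lapply(trial_ids, function(id) {
    sub <- df[df$trial_id == id, ]
    idx <- sub[sub$marker == "index", ]
    wri <- sub[sub$marker == "wrist", ]
    if (nrow(idx) == 0 || nrow(wri) == 0 || nrow(idx) != nrow(wri))
      stop("trial ", id, ": index/wrist samples missing or of unequal length")
    idx <- idx[order(idx$t_s), ]; wri <- wri[order(wri$t_s), ]
    dt <- diff(idx$t_s)
    if (length(dt) && (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-6))
      stop("trial ", id, ": non-uniform time base in column 't_s'")
    mi <- which(meta_ids == id)
    if (length(mi) != 1) stop("trial ", id, ": missing sidecar metadata")
    m <- side$trials[[mi]]
    ev <- lapply(m$events, num_or_na)
    structure(list(trial_id = as.integer(id),
                   participant_id = idx$participant[1],
                   experiment = as.integer(idx$experiment[1]),
                   dimension = idx$dimension[1],
                   condition = idx$condition[1],
                   initial_id = idx$initial_id[1],
                   final_id = idx$final_id[1],
                   t = idx$t_s,
                   index_xyz = as.matrix(idx[, c("x", "y", "z")]),
                   wrist_xyz = as.matrix(wri[, c("x", "y", "z")]),
                   events = ev[c("cue_on_s", "movement_onset_s", "shift_s",
                                 "touch_s")],
                   endpoint_touch_xy = as.numeric(unlist(m$endpoint_touch_xy)),
                   endpoint_planned_xy = as.numeric(unlist(m$endpoint_planned_xy)),
                   corrected = if (is.null(m$corrected)) NA else m$corrected,
                   correction_start_s = num_or_na(m$correction_start_s)),
              class = "reach_trial")
  })
  structure(list(participant_id = side$participant_id,
                 experiment = as.integer(side$experiment),
                 trials = trials,
                 layout = layout,
                 params = params),
            class = "reach_session")
}
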