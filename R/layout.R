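#' Target layout of the double-step reaching workspace
#'
#' Builds the 12-target arrangement used in the double-step reaching task:
#' four static targets placed on the cardinal axes at `static_distance` from
#' the central fixation point (left/right along x, the horizontal dimension;
#' near/far along y, the sagittal depth dimension), and eight shifted targets,
#' two children per static target, displaced by `shift_distance` along their
#' parent's dimension. All coordinates are centimetres on the screen plane,
#' fixation at the origin.
#'
#' Endpoint identifiers are `"left"`, `"right"`, `"near"`, `"far"` for the
#' static targets and `"<parent>_l"`/`"<parent>_r"` (horizontal) or
#' `"<parent>_n"`/`"<parent>_f"` (sagittal) for the shifted children.
#'
#' @param static_distance Distance (cm) from fixation to each static target.
#'   Default 8.
#' @param shift_distance Distance (cm) from a static target to each of its
#'   shifted children. Default 2.4.
#' @return An object of class `target_layout`: a list with `fixation` (length-2
#'   numeric), `static_targets` (4 x 2 matrix, row names = ids),
#'   `shifted_targets` (8 x 2 matrix), `parent` (named character vector mapping
#'   each shifted id to its static parent), `static_distance`,
#'   `shift_distance`.
#' @examples
#' lay <- target_layout()
#' sqrt(sum(lay$static_targets["right", ]^2))  # 8
#' @export
target_layout <- function(static_distance = 8, shift_distance = 2.4) {
  if (!is.numeric(static_distance) || length(static_distance) != 1 ||
      !is.finite(static_distance) || static_distance <= 0)
    stop("'static_distance' must be a single positive number")
  if (!is.numeric(shift_distance) || length(shift_distance) != 1 ||
      !is.finite(shift_distance) || shift_distance <= 0)
    stop("'shift_distance' must be a single positive number")

  d <- static_distance
  s <- shift_distance
  static <- rbind(
    left  = c(-d, 0),
    right = c( d, 0),
    near  = c(0, -d),
    far   = c(0,  d)
  )
  colnames(static) <- c("x", "y")

  shifted <- rbind(
    left_l  = static["left", ]  + c(-s, 0),
    left_r  = static["left", ]  + c( s, 0),
    right_l = static["right", ] + c(-s, 0),
    right_r = static["right", ] + c( s, 0),
    near_n  = static["near", ]  + c(0, -s),
    near_f  = static["near", ]  + c(0,  s),
    far_n   = static["far", ]   + c(0, -s),
    far_f   = static["far", ]   + c(0,  s)
  )
  parent <- c(left_l = "left", left_r = "left",
              right_l = "right", right_r = "right",
              near_n = "near", near_f = "near",
              far_n = "far", far_f = "far")

  structure(list(fixation = c(x = 0, y = 0),
                 static_targets = static,
                 shifted_targets = shifted,
                 parent = parent,
                 static_distance = static_distance,
                 shift_distance = shift_distance),
            class = "target_layout")
}

#' @export
print.target_layout <- function(x, ...) {
  cat("Double-step target layout\n")
  cat(sprintf("  static targets : %d at %.2f cm from fixation\n",
              nrow(x$static_targets), x$static_distance))
  cat(sprintf("  shifted targets: %d at %.2f cm from their static parent\n",
              nrow(x$shifted_targets), x$shift_distance))
  invisible(x)
}

# Dimension ("horizontal"/"sagittal") of a static endpoint id.
endpoint_dimension <- function(id) {
  ifelse(id %in% c("left", "right"), "horizontal", "sagittal")
}

# 2D position (cm) of any endpoint id in a layout.
endpoint_position <- function(layout, id) {
  if (id %in% rownames(layout$static_targets))
    return(layout$static_targets[id, ])
  if (id %in% rownames(layout$shifted_targets))
    return(layout$shifted_targets[id, ])
  stop("unknown endpoint id: ", id)
}
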