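#' Minimum-jerk point-to-point trajectory
#'
#' The smoothest straight reach between two points: position follows the
#' fifth-order polynomial profile \eqn{s(\tau) = 10\tau^3 - 15\tau^4 + 6\tau^5}
#' of normalized time \eqn{\tau = t/duration}, which has zero velocity and zero
#' acceleration at both ends and peak speed \eqn{1.875\,|goal-start|/duration}
#' at the midpoint. This is the simulator's movement kernel; corrective
#' submovements after a target shift are a second minimum-jerk profile
#' superposed on the first.
#'
#' @param start,goal Numeric vectors of equal length (positions, cm).
#' @param duration Movement duration in seconds (> 0).
#' @param n Number of samples (>= 2), equally spaced in time including both
#'   endpoints.
#' @return An `n x length(start)` matrix of positions; row 1 is `start`, row
#'   `n` is `goal`.
#' @examples
#' p <- minimum_jerk(c(0, 0, 0), c(10, 0, 0), duration = 1, n = 101)
#' max(diff(p[, 1]) / 0.01)  # ~18.75 cm/s
#' @export
minimum_jerk <- function(start, goal, duration, n) {
  if (length(start) != length(goal))
    stop("'start' and 'goal' must have the same length")
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0)
    stop("'duration' must be a single positive number")
  if (!is.numeric(n) || length(n) != 1 || n < 2)
    stop("'n' must be at least 2")
  tau <- seq(0, 1, length.out = n)
  s <- min_jerk_profile(tau)
  out <- outer(s, as.numeric(goal) - as.numeric(start))
  out <- sweep(out, 2, as.numeric(start), "+")
  out
}

# Scalar minimum-jerk progress profile s(tau) on [0, 1] (clamped outside).
min_jerk_profile <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  tau^3 * (10 - 15 * tau + 6 * tau^2)
}
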