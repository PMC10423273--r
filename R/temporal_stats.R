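#' Pointwise Hotelling-type comparison of accuracy curves
#'
#' Compares two groups of per-participant accuracy curves node by node with a
#' two-sample Hotelling T-squared statistic (which for these univariate
#' curves is the squared pooled-variance t statistic), controlling the
#' family-wise error across all nodes by the permutation distribution of the
#' maximum statistic: group labels are permuted `n_perm` times, the maximum
#' node statistic recorded each time, and nodes whose observed statistic
#' exceeds the `1 - alpha` quantile of that distribution are flagged.
#' Contiguous significant runs are reported as intervals in % of movement.
#'
#' @param curves_a,curves_b Matrices (participants x nodes) of accuracy
#'   curves on a common node grid, or lists of `goal_decoding` objects (their
#'   fold-averaged curves are stacked).
#' @param alpha Family-wise significance level (default 0.05).
#' @param n_perm Number of label permutations (default 1000). If the total
#'   number of distinct permutations is smaller, all are enumerated is not
#'   attempted; a warning notes the reduced resolution.
#' @param pct Node positions in % of movement; defaults to
#'   `end_index / 99 * 100` for 93-node curves built with T = 8, otherwise an
#'   even grid over 0-100.
#' @return An object of class `curve_comparison`: `statistic` (per node),
#'   `threshold`, `significant` (logical), `intervals` (matrix of
#'   `[start_pct, end_pct]`), `p_global` (permutation p of the curve maximum),
#'   `alpha`, `n_perm`, `pct`.
#' @export
hotelling_curve_test <- function(curves_a, curves_b, alpha = 0.05,
                                 n_perm = 1000, pct = NULL) {
  as_mat <- function(x) {
    if (is.list(x) && all(vapply(x, inherits, TRUE, "goal_decoding")))
      return(do.call(rbind, lapply(x, function(g) g$curve$accuracy)))
    as.matrix(x)
  }
  A <- as_mat(curves_a); B <- as_mat(curves_b)
  if (ncol(A) != ncol(B)) stop("curves must have equal length")
  n1 <- nrow(A); n2 <- nrow(B)
  if (n1 < 2 || n2 < 2) stop("need at least 2 curves per group")
  p <- ncol(A)
  if (is.null(pct)) {
    pct <- if (p == 93) (7:99) / 99 * 100 else seq(0, 100, length.out = p)
  }
  n_distinct <- choose(n1 + n2, n1)
  if (n_distinct < n_perm)
    warning("only ", n_distinct, " distinct group assignments exist; ",
            "permutation resolution is limited")

  t2_stat <- function(X, g1) {
    a <- X[g1, , drop = FALSE]; b <- X[!g1, , drop = FALSE]
    ma <- colMeans(a); mb <- colMeans(b)
    # pooled variance per node (univariate Hotelling T^2)
    sp <- (colSums((a - rep(ma, each = nrow(a)))^2) +
           colSums((b - rep(mb, each = nrow(b)))^2)) / (n1 + n2 - 2)
    stat <- (ma - mb)^2 / (sp * (1 / n1 + 1 / n2))
    stat[sp == 0] <- ifelse(abs(ma - mb)[sp == 0] > 0, Inf, 0)
    stat
  }
  X <- rbind(A, B)
  obs <- t2_stat(X, c(rep(TRUE, n1), rep(FALSE, n2)))
  max_perm <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    g <- logical(n1 + n2)
    g[sample.int(n1 + n2, n1)] <- TRUE
    max_perm[i] <- max(t2_stat(X, g))
  }
  threshold <- stats::quantile(max_perm, 1 - alpha, names = FALSE, type = 1)
  significant <- obs > threshold
  p_global <- (1 + sum(max_perm >= max(obs))) / (n_perm + 1)

  runs <- rle(significant)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  iv <- cbind(start_pct = pct[starts[runs$values]],
              end_pct = pct[ends[runs$values]])
  structure(list(statistic = obs, threshold = threshold,
                 significant = significant, intervals = iv,
                 p_global = p_global, alpha = alpha, n_perm = n_perm,
                 pct = pct, n_a = n1, n_b = n2),
            class = "curve_comparison")
}

#' @export
print.curve_comparison <- function(x, ...) {
  cat(sprintf("Curve comparison (%d vs %d curves, %d nodes, %d permutations)\n",
              x$n_a, x$n_b, length(x$statistic), x$n_perm))
  cat(sprintf("  max T2 = %.2f, threshold = %.2f, global p = %.4f\n",
              max(x$statistic), x$threshold, x$p_global))
  if (nrow(x$intervals) == 0) cat("  no significant interval\n")
  else for (i in seq_len(nrow(x$intervals)))
    cat(sprintf("  significant from %.1f%% to %.1f%% of movement\n",
                x$intervals[i, 1], x$intervals[i, 2]))
  invisible(x)
}

#' First sustained crossing of a level by an accuracy curve
#'
#' Returns the position, in % of movement, of the first node that begins a
#' run of at least `run_length` nodes with accuracy strictly above `level`
#' (the chance level, typically); `NA` if the curve never sustains the
#' crossing.
#'
#' @param curve A `goal_decoding` object, or a numeric accuracy vector.
#' @param level Level to exceed (default 0.5).
#' @param run_length Required run of consecutive supra-level nodes
#'   (default 3).
#' @param pct Node positions in % of movement; for a bare numeric curve the
#'   default maps node i (0-based) to `i / 99 * 100`.
#' @return Crossing position in % of movement, or `NA_real_`.
#' @export
chance_crossing_time <- function(curve, level = 0.5, run_length = 3,
                                 pct = NULL) {
  if (inherits(curve, "goal_decoding")) {
    if (is.null(pct)) pct <- curve$curve$pct_movement
    curve <- curve$curve$accuracy
  }
  curve <- as.numeric(curve)
  if (is.null(pct)) pct <- (seq_along(curve) - 1) / 99 * 100
  above <- curve > level
  n <- length(above)
  for (i in seq_len(n)) {
    if (i + run_length - 1 > n) break
    if (all(above[i:(i + run_length - 1)])) return(pct[i])
  }
  NA_real_
}

#' Confidence ellipse of a 2D point cloud
#'
#' Summarizes a bivariate sample by the eigendecomposition of its covariance
#' matrix: eigenvectors give the directions of greatest spread, eigenvalues
#' the variance along them. The ellipse covering a `coverage` fraction of a
#' bivariate normal population has semi-axes
#' \eqn{\sqrt{\chi^2_{2,coverage}\,\lambda_i}} and area \eqn{\pi a b}. The
#' raw-sigma area \eqn{\pi\sqrt{\lambda_1\lambda_2}} (semi-axes of one
#' standard deviation) is also reported.
#'
#' @param points An `n x 2` matrix/data frame (n >= 3).
#' @param coverage Coverage probability (default 0.95).
#' @return An object of class `confidence_ellipse`: `center`, `eigenvalues`
#'   (decreasing), `eigenvectors` (columns), `semi_axes`, `area`,
#'   `area_sigma`, `coverage`, `n`, `collinear` flag.
#' @export
confidence_ellipse <- function(points, coverage = 0.95) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2) stop("'points' must have 2 columns")
  if (nrow(pts) < 3) stop("need at least 3 points")
  if (coverage <= 0 || coverage >= 1) stop("'coverage' must be in (0, 1)")
  S <- stats::cov(pts)
  eg <- eigen(S, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  scale <- sqrt(stats::qchisq(coverage, df = 2))
  semi <- scale * sqrt(lambda)
  collinear <- lambda[2] <= 1e-12 * max(lambda[1], 1e-300)
  structure(list(center = colMeans(pts),
                 eigenvalues = lambda,
                 eigenvectors = eg$vectors,
                 semi_axes = semi,
                 area = pi * semi[1] * semi[2],
                 area_sigma = pi * sqrt(lambda[1] * lambda[2]),
                 coverage = coverage,
                 n = nrow(pts),
                 collinear = collinear),
            class = "confidence_ellipse")
}

#' @export
print.confidence_ellipse <- function(x, ...) {
  cat(sprintf("%.0f%% confidence ellipse of %d points\n",
              100 * x$coverage, x$n))
  cat(sprintf("  center (%.3g, %.3g); eigenvalues %.4g, %.4g; area %.4g%s\n",
              x$center[1], x$center[2], x$eigenvalues[1], x$eigenvalues[2],
              x$area, if (x$collinear) " (collinear points)" else ""))
  invisible(x)
}

#' @export
plot.confidence_ellipse <- function(x, points = NULL, ...) {
  th <- seq(0, 2 * pi, length.out = 200)
  circ <- rbind(x$semi_axes[1] * cos(th), x$semi_axes[2] * sin(th))
  ell <- t(x$eigenvectors %*% circ) + rep(x$center, each = 200)
  if (!is.null(points)) {
    graphics::plot(points, xlab = "x", ylab = "y", ...)
    graphics::lines(ell, lwd = 2)
  } else {
    graphics::plot(ell, type = "l", lwd = 2, xlab = "x", ylab = "y", ...)
  }
  graphics::points(x$center[1], x$center[2], pch = 3, cex = 1.5)
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov comparison of R-squared distributions
#'
#' Tests whether two collections of regression scores (e.g. the per-component
#' per-offset R-squared values from two experiments or two dimensions) come
#' from the same distribution.
#'
#' @param scores_a,scores_b Numeric vectors (>= 5 values each).
#' @return A list with `statistic` (KS D), `p_value`, sample sizes.
#' @export
compare_r2_distributions <- function(scores_a, scores_b) {
  a <- as.numeric(scores_a); b <- as.numeric(scores_b)
  if (length(a) < 5 || length(b) < 5) stop("need at least 5 values per sample")
  kt <- suppressWarnings(stats::ks.test(a, b))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       n_a = length(a), n_b = length(b))
}

#' Bonferroni-corrected two-sample t-test
#'
#' Welch two-sample t-test with significance declared at
#' `alpha / n_comparisons` — the explicit multiple-comparison thresholds used
#' when several condition pairs are tested together (e.g. 0.025 for 2
#' comparisons, 0.0125 for 4).
#'
#' @param a,b Numeric samples (>= 2 each).
#' @param alpha Nominal family alpha (default 0.05).
#' @param n_comparisons Number of comparisons in the family (default 1).
#' @return A list with `statistic`, `p_value`, `threshold`, `significant`.
#' @export
corrected_two_sample_test <- function(a, b, alpha = 0.05, n_comparisons = 1) {
  if (length(a) < 2 || length(b) < 2) stop("need at least 2 values per group")
  tt <- stats::t.test(a, b)
  threshold <- alpha / n_comparisons
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       threshold = threshold, significant = tt$p.value < threshold)
}
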