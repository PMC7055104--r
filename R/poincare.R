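# Poincare (lag-1 return map) descriptors and coefficient of variation.
#
# The Poincare plot scatters each sample x_n against its successor x_{n+1};
# an ellipse centred at the cloud's mean point with axes along and
# perpendicular to the line of identity summarises it. SD1 (minor semi-axis,
# dispersion perpendicular to the identity line) captures short-term
# variability; SD2 (major semi-axis, dispersion along it) long-term
# variability.

#' Build the lag-1 return-map cloud of a series
#'
#' Pairs consecutive retained samples `(x_n, x_{n+1})`. Pairs spanning a time
#' gap larger than `max_gap` are omitted, so dropout-induced gaps are not
#' conflated with physiologic variability.
#'
#' @param series a [bp_series] or a plain numeric vector (then a nominal 15-s
#'   spacing is assumed).
#' @param max_gap maximum admissible spacing between paired samples, seconds.
#'   Default 30 s = two nominal 15-s intervals, i.e. one missing sample may be
#'   bridged.
#' @return An object of class `lag1_cloud` with elements `x`, `y`, `n_pairs`.
#' @export
#' @examples
#' lag1_cloud(c(100, 105, 95, 110, 90))
lag1_cloud <- function(series, max_gap = 30) {
  if (inherits(series, "bp_series")) {
    v <- series$value_mmhg
    t <- series$time_s
    meta <- series[c("patient_id", "channel", "phase")]
  } else {
    v <- as.numeric(series)
    t <- (seq_along(v) - 1) * 15
    meta <- list(patient_id = NA_character_, channel = NA_character_,
                 phase = NA_character_)
  }
  n <- length(v)
  if (n < 2) {
    x <- y <- numeric(0)
  } else {
    keep <- diff(t) <= max_gap
    x <- v[-n][keep]
    y <- v[-1][keep]
  }
  structure(
    c(list(x = x, y = y, n_pairs = length(x), max_gap = max_gap), meta),
    class = "lag1_cloud"
  )
}

#' @export
print.lag1_cloud <- function(x, ...) {
  cat(sprintf("<lag1_cloud> %d pairs (max gap %.0f s)\n", x$n_pairs, x$max_gap))
  invisible(x)
}

new_poincare_sd <- function(sd1, sd2, n_pairs) {
  ratio <- if (is.na(sd2) || sd2 <= 0) NA_real_ else sd1 / sd2
  structure(list(sd1 = sd1, sd2 = sd2, ratio = ratio, n_pairs = n_pairs),
            class = "poincare_sd")
}

#' Poincare SD1/SD2 descriptors of a series or cloud
#'
#' Rotated-coordinate realisation of the 45-degree ellipse fit: SD1 is the
#' sample standard deviation of \eqn{(x_n - x_{n+1})/\sqrt{2}} over the lag-1
#' cloud, SD2 that of \eqn{(x_n + x_{n+1})/\sqrt{2}} (sample, n-1
#' denominator). Identical to projecting the mean-centred cloud onto the unit
#' directions perpendicular to and along the line of identity (see
#' [ellipse_fit_sd()]).
#'
#' Fewer than 2 admissible pairs yield `NA` descriptors (missing, not an
#' error); the SD1/SD2 ratio is `NA` when SD2 = 0.
#'
#' @param x a [lag1_cloud], [bp_series] or numeric vector.
#' @param max_gap passed to [lag1_cloud()] when `x` is not already a cloud.
#' @return An object of class `poincare_sd`: `sd1`, `sd2` (mmHg), `ratio`
#'   (SD1/SD2), `n_pairs`.
#' @export
#' @examples
#' poincare_sd(c(100, 105, 95, 110, 90))
poincare_sd <- function(x, max_gap = 30) {
  cloud <- if (inherits(x, "lag1_cloud")) x else lag1_cloud(x, max_gap)
  if (cloud$n_pairs < 2) {
    return(new_poincare_sd(NA_real_, NA_real_, cloud$n_pairs))
  }
  d1 <- (cloud$x - cloud$y) / sqrt(2)
  d2 <- (cloud$x + cloud$y) / sqrt(2)
  new_poincare_sd(stats::sd(d1), stats::sd(d2), cloud$n_pairs)
}

#' @export
print.poincare_sd <- function(x, ...) {
  cat(sprintf("<poincare_sd> SD1 = %.3f mmHg, SD2 = %.3f mmHg, SD1/SD2 = %s (%d pairs)\n",
              x$sd1, x$sd2,
              if (is.na(x$ratio)) "NA" else sprintf("%.3f", x$ratio),
              x$n_pairs))
  invisible(x)
}

#' Geometric ellipse-fit descriptors (test-support oracle)
#'
#' Independent construction of the same quantities as [poincare_sd()]: centre
#' the cloud at its mean point and take the standard deviations of the
#' projections onto the unit directions \eqn{(1,-1)/\sqrt 2} (perpendicular
#' to the line of identity) and \eqn{(1,1)/\sqrt 2} (along it). Algebraically
#' identical to the rotated-coordinate formulas; kept separate as a
#' validation oracle and as the geometry source for [plot_poincare()].
#'
#' @param cloud a [lag1_cloud].
#' @return An object of class `poincare_sd`.
#' @export
ellipse_fit_sd <- function(cloud) {
  stopifnot(inherits(cloud, "lag1_cloud"))
  if (cloud$n_pairs < 2) {
    return(new_poincare_sd(NA_real_, NA_real_, cloud$n_pairs))
  }
  pts <- cbind(cloud$x, cloud$y)
  cen <- sweep(pts, 2, colMeans(pts))
  p1 <- as.vector(cen %*% (c(1, -1) / sqrt(2)))
  p2 <- as.vector(cen %*% (c(1, 1) / sqrt(2)))
  n <- length(p1)
  new_poincare_sd(sqrt(sum(p1^2) / (n - 1)), sqrt(sum(p2^2) / (n - 1)), n)
}

#' Coefficient of variation of a pressure series
#'
#' CV = sample standard deviation divided by sample mean, over all samples in
#' the series (time gaps are irrelevant). Undefined (`NA`) for fewer than 2
#' samples or non-positive mean.
#'
#' @param x a [bp_series] or numeric vector.
#' @return An object of class `bp_cv`: `cv`, `mean` (mmHg), `sd` (mmHg), `n`.
#' @export
#' @examples
#' cv_bp(c(100, 110, 90, 100))   # mean 100, sd 8.165, cv 0.0816
cv_bp <- function(x) {
  v <- if (inherits(x, "bp_series")) x$value_mmhg else as.numeric(x)
  n <- length(v)
  if (n < 2) {
    return(structure(list(cv = NA_real_, mean = if (n) mean(v) else NA_real_,
                          sd = NA_real_, n = n), class = "bp_cv"))
  }
  m <- mean(v)
  s <- stats::sd(v)
  cv <- if (m > 0) s / m else NA_real_
  structure(list(cv = cv, mean = m, sd = s, n = n), class = "bp_cv")
}

#' @export
print.bp_cv <- function(x, ...) {
  cat(sprintf("<bp_cv> CV = %s (mean %.2f mmHg, SD %.3f mmHg, n = %d)\n",
              if (is.na(x$cv)) "NA" else sprintf("%.4f", x$cv),
              x$mean, x$sd, x$n))
  invisible(x)
}

#' Plot a Poincare return map with its fitted ellipse
#'
#' Scatter of `x_n` against `x_{n+1}` with the line of identity, the fitted
#' ellipse (semi-axes SD2 along the identity line, SD1 perpendicular to it,
#' centred at the cloud's mean point) and the two semi-axes drawn as arrows.
#'
#' @param x a [bp_series], [lag1_cloud] or numeric vector.
#' @param max_gap pairing gap rule, seconds.
#' @param main plot title.
#' @param ... further arguments passed to [graphics::plot()].
#' @return Invisibly, the `poincare_sd` descriptors.
#' @export
plot_poincare <- function(x, max_gap = 30, main = "Poincaré plot", ...) {
  cloud <- if (inherits(x, "lag1_cloud")) x else lag1_cloud(x, max_gap)
  if (cloud$n_pairs < 2) stop("need at least 2 lag-1 pairs to plot")
  ds <- ellipse_fit_sd(cloud)
  cx <- mean(cloud$x)
  cy <- mean(cloud$y)
  graphics::plot(cloud$x, cloud$y, pch = 16, cex = 0.4, col = "grey40",
                 xlab = expression(x[n] ~ (mmHg)),
                 ylab = expression(x[n + 1] ~ (mmHg)),
                 main = main, asp = 1, ...)
  graphics::abline(0, 1, lty = 2, col = "grey60")
  th <- seq(0, 2 * pi, length.out = 181)
  u_id <- c(1, 1) / sqrt(2)
  u_pp <- c(-1, 1) / sqrt(2)
  ex <- cx + ds$sd2 * cos(th) * u_id[1] + ds$sd1 * sin(th) * u_pp[1]
  ey <- cy + ds$sd2 * cos(th) * u_id[2] + ds$sd1 * sin(th) * u_pp[2]
  graphics::lines(ex, ey, col = "firebrick", lwd = 2)
  graphics::arrows(cx, cy, cx + ds$sd2 * u_id[1], cy + ds$sd2 * u_id[2],
                   length = 0.08, col = "navy", lwd = 2)
  graphics::arrows(cx, cy, cx + ds$sd1 * u_pp[1], cy + ds$sd1 * u_pp[2],
                   length = 0.08, col = "darkgreen", lwd = 2)
  graphics::legend("topleft", bty = "n", cex = 0.8,
                   legend = c(sprintf("SD1 = %.2f mmHg", ds$sd1),
                              sprintf("SD2 = %.2f mmHg", ds$sd2)))
  invisible(ds)
}
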