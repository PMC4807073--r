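# Logan graphical analysis for reversible tracers.
#
# With a reference-tissue input the late-time slope of
#   int_0^t C_T / C_T(t)  versus  [int_0^t C_R + C_R(t)/k2'] / C_T(t)
# estimates the distribution volume ratio DVR (BP_ND = DVR - 1); the
# C_R/k2' term is omitted by default, the common practice for PiB, and
# can be enabled through `k2prime`. With an arterial plasma input the
# slope of int_0^t C_T / C_T(t) versus int_0^t C_p / C_T(t) estimates the
# total volume of distribution V_T.

#' Cumulative trapezoidal integral of a TAC from time zero
#'
#' Integrates the piecewise-linear curve through (0, 0) and the frame
#' (mid-time, value) points; returns the running integral at each frame
#' mid-time. Non-decreasing for non-negative TACs.
#'
#' @param tac A [tac()].
#' @return Numeric vector, kBq*min/mL, one value per frame.
#' @export
cumulative_integral <- function(tac) {
  t <- c(0, tac$mid_times)
  v <- c(0, tac$values)
  cumsum(diff(t) * (v[-length(v)] + v[-1L]) / 2)
}

# Running trapezoid on an arbitrary (t, v) grid, anchored at (0, 0) when
# the grid starts after zero.
.cum_trapz <- function(t, v) {
  prepended <- t[1L] > 0
  if (prepended) {
    t <- c(0, t)
    v <- c(0, v)
  }
  out <- cumsum(c(0, diff(t) * (v[-length(v)] + v[-1L]) / 2))
  if (prepended) out[-1L] else out
}

.logan_ols <- function(x, y) {
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- unname(fit$coefficients[2L])
  intercept <- unname(fit$coefficients[1L])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else max(0, min(1, 1 - ss_res / ss_tot))
  list(slope = slope, intercept = intercept, r_squared = r2)
}

.new_logan_fit <- function(fit, x, y, tstar, variant) {
  structure(list(
    slope = fit$slope, intercept = fit$intercept,
    bp_nd = if (variant == "reference") fit$slope - 1 else NULL,
    tstar = tstar, n_points = length(x), r_squared = fit$r_squared,
    x = x, y = y, variant = variant),
    class = "logan_fit")
}

#' Logan graphical analysis with a reference-tissue input
#'
#' Ordinary least squares of the Logan transform over all frames with
#' mid-time >= `tstar`; the slope is the distribution volume ratio (DVR)
#' and BP_ND = DVR - 1.
#'
#' @param target Target-region [tac()].
#' @param reference Reference-region [tac()] on the same frame grid.
#' @param tstar Start of the linear fit window, minutes (default 30).
#' @param k2prime Reference-region efflux constant (1/min) for the full
#'   Logan reference-tissue ordinate, or `NULL` (default) to omit the
#'   `C_R / k2'` term.
#' @param weighted Weight the fit by frame durations (default FALSE,
#'   unweighted OLS).
#' @return An object of class `logan_fit`; `coef()` returns the slope
#'   (DVR) and intercept, `$bp_nd` holds DVR - 1.
#' @export
logan_reference <- function(target, reference, tstar = 30, k2prime = NULL,
                            weighted = FALSE) {
  if (length(target) != length(reference) ||
      max(abs(target$mid_times - reference$mid_times)) > 1e-9)
    stop("target and reference must share one frame grid")
  keep <- target$mid_times >= tstar - 1e-9
  if (sum(keep) < 3L)
    stop("need >= 3 frames with mid-time >= tstar")
  if (any(target$values[keep] <= 0))
    stop("target TAC must be positive in the fit window")
  int_t <- cumulative_integral(target)[keep]
  int_r <- cumulative_integral(reference)[keep]
  ct <- target$values[keep]
  cr <- reference$values[keep]
  y <- int_t / ct
  x <- if (is.null(k2prime)) int_r / ct else (int_r + cr / k2prime) / ct
  fit <- if (weighted)
    .wls(x, y, target$durations[keep]) else .logan_ols(x, y)
  .new_logan_fit(fit, x, y, tstar, "reference")
}

.wls <- function(x, y, w) {
  fit <- stats::lm.wfit(cbind(1, x), y, w)
  ss_res <- sum(w * fit$residuals^2)
  yb <- sum(w * y) / sum(w)
  ss_tot <- sum(w * (y - yb)^2)
  list(slope = unname(fit$coefficients[2L]),
       intercept = unname(fit$coefficients[1L]),
       r_squared = if (ss_tot == 0) 1 else max(0, min(1, 1 - ss_res / ss_tot)))
}

#' Logan graphical analysis with an arterial plasma input
#'
#' The input must already be metabolite-corrected (see
#' [apply_parent_fraction()]) or carry `parent_fraction == 1`. The plasma
#' integral is computed by trapezoid on the input's native time grid and
#' interpolated linearly to the frame mid-times.
#'
#' @param target Target-region [tac()].
#' @param input An [input_function()] covering `[0, last frame mid-time]`.
#' @param tstar Start of the fit window, minutes (default 30).
#' @param weighted Weight by frame durations (default FALSE).
#' @return A `logan_fit`; the slope is V_T.
#' @export
logan_plasma <- function(target, input, tstar = 30, weighted = FALSE) {
  if (!all(input$parent_fraction == 1))
    stop("input carries an unapplied parent fraction; ",
         "call apply_parent_fraction() first")
  t_end <- target$mid_times[length(target)]
  if (input$times[length(input$times)] < t_end - 1e-9)
    stop(sprintf(
      "input does not cover scan: input ends %.3g min, scan needs %.3g min",
      input$times[length(input$times)], t_end))
  keep <- target$mid_times >= tstar - 1e-9
  if (sum(keep) < 3L)
    stop("need >= 3 frames with mid-time >= tstar")
  if (any(target$values[keep] <= 0))
    stop("target TAC must be positive in the fit window")
  int_p_native <- .cum_trapz(input$times, input$total_plasma)
  int_p <- stats::approx(input$times, int_p_native,
                         xout = target$mid_times[keep], rule = 2)$y
  ct <- target$values[keep]
  y <- cumulative_integral(target)[keep] / ct
  x <- int_p / ct
  fit <- if (weighted)
    .wls(x, y, target$durations[keep]) else .logan_ols(x, y)
  .new_logan_fit(fit, x, y, tstar, "plasma")
}

#' Apply a population parent-fraction curve to an input function
#'
#' Multiplies total plasma activity pointwise by the parent fraction
#' (metabolite correction) and resets the fraction to 1.
#'
#' @param input An [input_function()].
#' @return A metabolite-corrected [input_function()].
#' @export
apply_parent_fraction <- function(input) {
  input_function(input$times, input$total_plasma * input$parent_fraction,
                 rep(1, length(input$times)))
}

#' @export
print.logan_fit <- function(x, ...) {
  if (x$variant == "reference") {
    cat(sprintf(
      "Logan reference-tissue fit: DVR = %.4f (BP_ND = %.4f)\n",
      x$slope, x$bp_nd))
  } else {
    cat(sprintf("Logan plasma-input fit: V_T = %.4f\n", x$slope))
  }
  cat(sprintf("  t* = %g min, %d points, intercept %.4g min, R^2 = %.6f\n",
              x$tstar, x$n_points, x$intercept, x$r_squared))
  invisible(x)
}

#' @export
coef.logan_fit <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' @export
predict.logan_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else as.numeric(newdata)
  object$intercept + object$slope * x
}

#' @export
residuals.logan_fit <- function(object, ...) {
  object$y - predict(object)
}

#' @export
summary.logan_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
plot.logan_fit <- function(x, ...) {
  graphics::plot(x$x, x$y,
                 xlab = if (x$variant == "reference")
                   "int C_R / C_T (min)" else "int C_p / C_T (min)",
                 ylab = "int C_T / C_T (min)",
                 main = sprintf("Logan plot (slope %.3f)", x$slope), ...)
  graphics::abline(x$intercept, x$slope, col = "red3")
  invisible(x)
}
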