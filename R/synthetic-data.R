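# Synthetic-data generators: analytic input functions, compartment-model
# time-activity curves, digital label phantoms with PSF blur and noise,
# and longitudinal visit-pair cohorts. Every generator carries its ground
# truth so the estimators can be validated end to end.

.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed)
    old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed)
      assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Default 70-minute dynamic PiB-like frame schedule
#'
#' 4 x 15 s, 8 x 30 s, 9 x 60 s, 2 x 180 s, 10 x 300 s: 33 frames
#' totalling 70 minutes.
#'
#' @return A [frame_schedule()].
#' @export
default_frame_schedule <- function() {
  durations <- c(rep(0.25, 4), rep(0.5, 8), rep(1, 9), rep(3, 2), rep(5, 10))
  ends <- cumsum(durations)
  frame_schedule(ends - durations, ends)
}

#' Peaked tri-exponential (Feng-type) input-function parameters
#'
#' The curve is zero before the appearance `delay`, rises to a single
#' early peak and decays as
#' `(A1*t' - A2 - A3) exp(-l1 t') + A2 exp(-l2 t') + A3 exp(-l3 t')`
#' with `t'` the time since appearance. Amplitudes are in kBq/mL
#' (A1 kBq/mL/min), rate constants in 1/min.
#'
#' @param A1,A2,A3 Amplitudes; the curve is linear in these.
#' @param l1,l2,l3 Decay constants (1/min).
#' @param delay Appearance delay, minutes.
#' @return Named list of parameters.
#' @export
input_shape_params <- function(A1 = 851.1, A2 = 21.9, A3 = 20.8,
                               l1 = 4.1339, l2 = 0.01043, l3 = 0.1191,
                               delay = 0.5) {
  list(A1 = A1, A2 = A2, A3 = A3, l1 = l1, l2 = l2, l3 = l3, delay = delay)
}

.eval_input_curve <- function(p, t) {
  tp <- t - p$delay
  v <- ifelse(tp <= 0, 0,
              (p$A1 * tp - p$A2 - p$A3) * exp(-p$l1 * tp) +
                p$A2 * exp(-p$l2 * tp) + p$A3 * exp(-p$l3 * tp))
  v
}

#' Simulate an arterial input function
#'
#' Deterministic analytic curve from [input_shape_params()], evaluated at
#' the requested sample times.
#'
#' @param shape_params Parameter list from [input_shape_params()].
#' @param times Sample times, minutes, covering `[0, end of scan]`.
#' @return An [input_function()] with `parent_fraction = 1`.
#' @export
simulate_input_function <- function(shape_params = input_shape_params(),
                                    times = seq(0, 70, by = 0.1)) {
  v <- .eval_input_curve(shape_params, times)
  dense <- .eval_input_curve(shape_params,
                             seq(min(times), max(times), length.out = 5000L))
  if (any(dense < -1e-9))
    stop("shape parameters yield a negative input curve")
  input_function(times, pmax(v, 0))
}

#' Compartment-model specification with derived ground truth
#'
#' One-tissue: V_T = K1/k2. Two-tissue reversible: V_T =
#' (K1/k2) (1 + k3/k4), BP_ND = k3/k4.
#'
#' @param model `"one_tissue"` or `"two_tissue"`.
#' @param K1 Delivery, mL/mL/min, > 0.
#' @param k2 Efflux, 1/min, > 0.
#' @param k3,k4 Exchange with the bound compartment, 1/min (two-tissue
#'   only), > 0.
#' @return An object of class `compartment_spec` with `true_vt` and (for
#'   two-tissue) `true_bpnd`.
#' @export
compartment_spec <- function(model = c("one_tissue", "two_tissue"),
                             K1, k2, k3 = NULL, k4 = NULL) {
  model <- match.arg(model)
  if (!(K1 > 0) || !(k2 > 0))
    stop("K1 and k2 must be > 0")
  if (model == "two_tissue") {
    if (is.null(k3) || is.null(k4) || !(k3 > 0) || !(k4 > 0))
      stop("two-tissue model needs k3 > 0 and k4 > 0")
    true_vt <- K1 / k2 * (1 + k3 / k4)
    true_bpnd <- k3 / k4
  } else {
    k3 <- k4 <- NULL
    true_vt <- K1 / k2
    true_bpnd <- NULL
  }
  structure(list(model = model, K1 = K1, k2 = k2, k3 = k3, k4 = k4,
                 true_vt = true_vt, true_bpnd = true_bpnd),
            class = "compartment_spec")
}

#' @export
print.compartment_spec <- function(x, ...) {
  cat(sprintf("%s compartment model: V_T = %.4g%s\n",
              if (x$model == "one_tissue") "One-tissue" else "Two-tissue",
              x$true_vt,
              if (is.null(x$true_bpnd)) ""
              else sprintf(", BP_ND = %.4g", x$true_bpnd)))
  invisible(x)
}

# conv(exp(-lambda t), f)(t) on a uniform grid, exact for piecewise-linear
# f: a stable one-step recursion evaluated with stats::filter.
.exp_conv <- function(lambda, h, f) {
  n <- length(f)
  E <- exp(-lambda * h)
  a <- f[-n]; b <- f[-1L]
  contrib <- a * (1 - E) / lambda +
    (b - a) / h * (h / lambda - (1 - E) / lambda^2)
  c(0, as.numeric(stats::filter(contrib, E, method = "recursive")))
}

#' Simulate a tissue time-activity curve from a compartment model
#'
#' Solves the compartment kinetics by exact exponential-kernel
#' convolution of the (piecewise-linear) input on a fine uniform grid,
#' then averages the solution within each frame. The ground-truth V_T
#' (and BP_ND for two-tissue) travels as attributes `true_vt` /
#' `true_bpnd`.
#'
#' @param spec A [compartment_spec()].
#' @param input An [input_function()] covering the schedule.
#' @param schedule A [frame_schedule()].
#' @param step Fine-grid step, minutes (default 0.01, the resolution at
#'   which the piecewise-linear input is sampled).
#' @return A [tac()] on `schedule`.
#' @export
simulate_tissue_tac <- function(spec, input, schedule, step = 0.01) {
  t_end <- schedule$end[nrow(schedule)]
  if (input$times[length(input$times)] < t_end - 1e-9)
    stop("input does not cover the frame schedule")
  t_fine <- seq(0, t_end, by = step)
  tt <- input$times
  vv <- input$total_plasma
  if (tt[1L] > 0) {
    tt <- c(0, tt)
    vv <- c(0, vv)
  }
  cp <- stats::approx(tt, vv, xout = t_fine, rule = 2)$y
  if (spec$model == "one_tissue") {
    ct <- spec$K1 * .exp_conv(spec$k2, step, cp)
  } else {
    s <- spec$k2 + spec$k3 + spec$k4
    disc <- sqrt(s^2 - 4 * spec$k2 * spec$k4)
    a1 <- (s - disc) / 2
    a2 <- (s + disc) / 2
    ct <- spec$K1 / (a2 - a1) *
      ((spec$k3 + spec$k4 - a1) * .exp_conv(a1, step, cp) +
         (a2 - spec$k3 - spec$k4) * .exp_conv(a2, step, cp))
  }
  vals <- vapply(seq_len(nrow(schedule)), function(i) {
    inside <- t_fine >= schedule$start[i] - 1e-9 &
      t_fine <= schedule$end[i] + 1e-9
    mean(ct[inside])
  }, numeric(1))
  out <- tac_on_schedule(schedule, vals)
  attr(out, "true_vt") <- spec$true_vt
  attr(out, "true_bpnd") <- spec$true_bpnd
  out
}

#' Digital phantom specification
#'
#' @param grid Integer length-3 grid shape, voxels.
#' @param voxel_size mm per axis (length 1 or 3).
#' @param regions List of region descriptions, each a list with fields
#'   `name`, `shape` (`"box"` or `"ellipsoid"`), `center` (voxel
#'   coordinates), `extent` (full widths for a box / semi-axes doubled
#'   for an ellipsoid, in voxels), and `value`: a scalar true activity,
#'   a per-frame vector of true activities, or a [compartment_spec()]
#'   (which requires `input`).
#' @param background Background true activity (default 0).
#' @param psf A [psf_model()] applied to each frame (default: none).
#' @param noise_sd Zero-mean Gaussian voxel noise SD, kBq/mL (default 0).
#' @param seed RNG seed for the noise.
#' @param schedule A [frame_schedule()] (default: one 40-70 min frame).
#' @param input An [input_function()], needed only when a region value is
#'   a [compartment_spec()].
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid, voxel_size = 2, regions, background = 0,
                         psf = psf_model(0), noise_sd = 0, seed = 1,
                         schedule = frame_schedule(40, 70), input = NULL) {
  grid <- as.integer(grid)
  if (length(grid) != 3L || any(grid < 1L))
    stop("grid must be three positive integers")
  if (length(voxel_size) == 1L)
    voxel_size <- rep(voxel_size, 3L)
  if (noise_sd < 0)
    stop("noise_sd must be >= 0")
  nms <- vapply(regions, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate phantom region names")
  structure(list(grid = grid, voxel_size = as.numeric(voxel_size),
                 regions = regions, background = background, psf = psf,
                 noise_sd = noise_sd, seed = seed, schedule = schedule,
                 input = input), class = "phantom_spec")
}

.primitive_mask <- function(grid, region) {
  idx <- expand.grid(x = seq_len(grid[1L]), y = seq_len(grid[2L]),
                     z = seq_len(grid[3L]))
  ctr <- region$center
  ext <- region$extent
  if (length(ext) == 1L) ext <- rep(ext, 3L)
  m <- switch(region$shape,
    box = abs(idx$x - ctr[1L]) <= ext[1L] / 2 + 1e-9 &
          abs(idx$y - ctr[2L]) <= ext[2L] / 2 + 1e-9 &
          abs(idx$z - ctr[3L]) <= ext[3L] / 2 + 1e-9,
    ellipsoid = ((idx$x - ctr[1L]) / (ext[1L] / 2))^2 +
                ((idx$y - ctr[2L]) / (ext[2L] / 2))^2 +
                ((idx$z - ctr[3L]) / (ext[3L] / 2))^2 <= 1 + 1e-9,
    stop("unknown primitive shape: ", region$shape))
  array(m, dim = grid)
}

#' Build a digital label phantom with known regional truth
#'
#' Paints each region's true activity (constant, per-frame vector, or a
#' frame-averaged compartment-model TAC) into its geometric primitive,
#' convolves every frame with the PSF, and adds seeded zero-mean Gaussian
#' noise. The returned truth table is untouched by blur and noise.
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `labels` (a [label_volume()], region i
#'   painted as label i), `pet` (the degraded [dynamic_volume()]),
#'   `truth` (data frame region x frame x true value), and `scheme` (an
#'   [roi_scheme()] naming each region's label).
#' @export
build_digital_phantom <- function(spec) {
  grid <- spec$grid
  nf <- n_frames(spec$schedule)
  labels <- array(0L, dim = grid)
  true_frames <- vector("list", length(spec$regions))
  masks <- vector("list", length(spec$regions))
  for (i in seq_along(spec$regions)) {
    reg <- spec$regions[[i]]
    m <- .primitive_mask(grid, reg)
    if (!any(m))
      stop("empty primitive for region ", reg$name)
    if (any(labels[m] != 0L))
      stop("overlapping primitives: region ", reg$name)
    labels[m] <- i
    masks[[i]] <- m
    val <- reg$value
    if (inherits(val, "compartment_spec")) {
      if (is.null(spec$input))
        stop("phantom spec needs an input function for compartment regions")
      val <- simulate_tissue_tac(val, spec$input, spec$schedule)$values
    }
    if (!length(val) %in% c(1L, nf))
      stop("region value must be scalar or one value per frame")
    true_frames[[i]] <- rep_len(as.numeric(val), nf)
  }
  vox <- array(0, dim = c(grid, nf))
  noise <- if (spec$noise_sd > 0)
    .with_seed(spec$seed,
               array(stats::rnorm(prod(grid) * nf, sd = spec$noise_sd),
                     dim = c(grid, nf)))
  else NULL
  for (f in seq_len(nf)) {
    frame <- array(spec$background, dim = grid)
    for (i in seq_along(masks))
      frame[masks[[i]]] <- true_frames[[i]][f]
    if (any(spec$psf$fwhm > 0))
      frame <- gaussian_blur(frame, spec$psf, spec$voxel_size)
    if (!is.null(noise))
      frame <- frame + noise[, , , f]
    vox[, , , f] <- frame
  }
  region_names <- vapply(spec$regions, `[[`, character(1), "name")
  truth <- data.frame(
    region = rep(region_names, each = nf),
    frame = rep(seq_len(nf), times = length(region_names)),
    value = unlist(true_frames))
  list(labels = label_volume(labels, spec$voxel_size),
       pet = dynamic_volume(vox, spec$voxel_size, spec$schedule),
       truth = truth,
       scheme = roi_scheme(stats::setNames(as.list(seq_along(region_names)),
                                           region_names)))
}

#' Simulated longitudinal cohort specification
#'
#' Defaults emulate a longitudinal mutation-carrier cohort measured with
#' a white-matter-referenced cortical SUVR: n = 59 visit pairs, baseline
#' 1.08 +/- 0.31, annual accumulation rate 0.02 +/- 0.04 per year,
#' interval 1.7 +/- 0.8 years (truncated above 0.1 years), and a
#' measurement noise SD of 0.02 SUVR per visit.
#'
#' @param n Number of subjects (>= 2).
#' @param baseline_mean,baseline_sd True baseline distribution.
#' @param rate_mean,rate_sd True annual-rate distribution (per year).
#' @param interval_mean,interval_sd Scan-interval distribution, years
#'   (truncated > 0.1).
#' @param noise_sd Measurement noise SD added independently to each visit.
#' @param seed RNG seed.
#' @return An object of class `sim_cohort_spec`.
#' @export
sim_cohort_spec <- function(n = 59, baseline_mean = 1.08,
                            baseline_sd = 0.31, rate_mean = 0.02,
                            rate_sd = 0.04, interval_mean = 1.7,
                            interval_sd = 0.8, noise_sd = 0.02, seed = 1) {
  if (n < 2L) stop("n must be >= 2")
  if (baseline_sd < 0 || rate_sd < 0 || interval_sd < 0 || noise_sd < 0)
    stop("SDs must be >= 0")
  if (interval_sd == 0 && interval_mean <= 0.1)
    stop("interval_mean must exceed the 0.1-year truncation floor")
  structure(list(n = as.integer(n), baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, rate_mean = rate_mean,
                 rate_sd = rate_sd, interval_mean = interval_mean,
                 interval_sd = interval_sd, noise_sd = noise_sd,
                 seed = seed), class = "sim_cohort_spec")
}

#' Simulate a longitudinal visit-pair cohort
#'
#' Per subject, a true baseline and true annual rate are drawn from the
#' stated normals and the interval from a truncated normal (> 0.1 yr);
#' `m1 = baseline + noise`, `m2 = baseline + rate * interval + noise`
#' with independent measurement noise per visit. The true per-subject
#' rates are attached as attribute `true_rate`.
#'
#' @param spec A [sim_cohort_spec()].
#' @return A [longitudinal_cohort()].
#' @export
simulate_longitudinal_cohort <- function(spec = sim_cohort_spec()) {
  .with_seed(spec$seed, {
    n <- spec$n
    baseline <- stats::rnorm(n, spec$baseline_mean, spec$baseline_sd)
    rate <- stats::rnorm(n, spec$rate_mean, spec$rate_sd)
    interval <- stats::rnorm(n, spec$interval_mean, spec$interval_sd)
    for (i in which(interval <= 0.1)) {
      while (interval[i] <= 0.1)
        interval[i] <- stats::rnorm(1, spec$interval_mean, spec$interval_sd)
    }
    m1 <- baseline + stats::rnorm(n, 0, spec$noise_sd)
    m2 <- baseline + rate * interval + stats::rnorm(n, 0, spec$noise_sd)
    out <- longitudinal_cohort(sprintf("sim%03d", seq_len(n)), m1, m2,
                               interval)
    attr(out, "true_rate") <- rate
    out
  })
}
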