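# Independent brute-force oracles. These re-derive each statistic from
# its textbook formula (never through the package's code path) so the
# implementation and the check stay on separate routes.

oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * stats::pt(-abs(t), na + nb - 2)
  list(t = t, p = p)
}

oracle_paired_t <- function(baseline, followup) {
  d <- followup - baseline
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), n - 1))
}

oracle_pearson <- function(a, b) {
  n <- length(a)
  r <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

oracle_change_summary <- function(m1, m2, interval) {
  delta <- m2 - m1
  rate <- delta / interval
  list(mean_delta = sum(delta) / length(delta),
       sd_delta = sqrt(sum((delta - mean(delta))^2) / (length(delta) - 1)),
       mean_rate = mean(rate), sd_rate = stats::sd(rate),
       mean_delta_pct = mean(100 * delta / m1),
       effect_size_d = mean(rate) / stats::sd(rate))
}

# Dense brute-force separable Gaussian blur: explicit triple loop over
# kernel offsets, zero-padded. Independent of the package's
# convolution-matrix route.
oracle_blur_3d <- function(arr, fwhm, voxel_size) {
  d <- dim(arr)
  sig <- fwhm / (2 * sqrt(2 * log(2))) / voxel_size
  for (ax in 1:3) {
    if (sig[ax] <= 0) next
    r <- max(1L, ceiling(4 * sig[ax]))
    k <- -r:r
    w <- stats::pnorm((k + 0.5) / sig[ax]) - stats::pnorm((k - 0.5) / sig[ax])
    w <- w / sum(w)
    out <- array(0, dim = d)
    for (j in seq_along(k)) {
      src <- seq_len(d[ax]) - k[j]
      ok <- src >= 1 & src <= d[ax]
      idx_to <- which(ok)
      idx_from <- src[ok]
      if (ax == 1) out[idx_to, , ] <- out[idx_to, , ] + w[j] * arr[idx_from, , ]
      if (ax == 2) out[, idx_to, ] <- out[, idx_to, ] + w[j] * arr[, idx_from, ]
      if (ax == 3) out[, , idx_to] <- out[, , idx_to] + w[j] * arr[, , idx_from]
    }
    arr <- out
  }
  arr
}

# Monte-Carlo power of a pooled two-sample t-test comparing treated
# (reduced-rate) and placebo arms; vectorized over trials.
oracle_mc_power <- function(n, mean_rate, sd_rate, reduction,
                            alpha = 0.05, reps = 10000) {
  placebo <- matrix(stats::rnorm(reps * n, mean_rate, sd_rate), reps)
  treated <- matrix(stats::rnorm(reps * n, (1 - reduction) * mean_rate,
                                 sd_rate), reps)
  sp <- sqrt((apply(placebo, 1, stats::var) +
                apply(treated, 1, stats::var)) / 2)
  t <- (rowMeans(placebo) - rowMeans(treated)) / (sp * sqrt(2 / n))
  mean(abs(t) > stats::qt(1 - alpha / 2, 2 * n - 2))
}

# A four-region phantom spec exercising boxes and ellipsoids on a shared
# grid, reused across PVC tests and acceptance checks.
four_region_phantom_spec <- function(grid = c(64, 64, 64), values = c(10, 4, 7, 2),
                                     background = 1, fwhm = 6, noise_sd = 0,
                                     schedule = frame_schedule(40, 70),
                                     seed = 1) {
  phantom_spec(
    grid = grid, voxel_size = 2,
    regions = list(
      list(name = "cortex", shape = "box", center = grid * c(0.3, 0.5, 0.5),
           extent = grid * c(0.22, 0.28, 0.28), value = values[[1]]),
      list(name = "cerebellum", shape = "ellipsoid",
           center = grid * c(0.68, 0.5, 0.3), extent = grid * c(0.19, 0.19, 0.12),
           value = values[[2]]),
      list(name = "white_matter", shape = "box",
           center = grid * c(0.68, 0.5, 0.72), extent = grid * c(0.12, 0.16, 0.12),
           value = values[[3]]),
      list(name = "brainstem", shape = "ellipsoid",
           center = grid * c(0.5, 0.8, 0.5), extent = grid * c(0.12, 0.12, 0.12),
           value = values[[4]])),
    background = background, psf = psf_model(fwhm), noise_sd = noise_sd,
    seed = seed, schedule = schedule)
}

# Observed per-region means (region order of a GTM system) for one frame.
observed_region_means <- function(phantom, system, frame = 1L) {
  vapply(system$region_order, function(nm) {
    ids <- if (nm == ".background") 0L else phantom$scheme$regions[[nm]]
    extract_tac(phantom$pet, phantom$labels, ids)$values[frame]
  }, numeric(1))
}

phantom_truth_vector <- function(phantom, system, background, frame = 1L) {
  truth <- phantom$truth[phantom$truth$frame == frame, ]
  vals <- stats::setNames(truth$value, truth$region)
  out <- vals[setdiff(system$region_order, ".background")]
  if (".background" %in% system$region_order)
    out <- c(out, .background = background)
  out
}
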