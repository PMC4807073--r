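# Longitudinal statistics: visit-pair change metrics, paired tests,
# Cohen's d on the annual rate of change, test-retest variability, and
# clinical-trial sample-size estimation from the observed rate.

#' Longitudinal visit-pair cohort
#'
#' @param subject Subject identifiers.
#' @param m1 Baseline amyloid-burden measurements (unitless, e.g. MCSUVR).
#' @param m2 Follow-up measurements.
#' @param interval Scan interval in years, > 0.
#' @return A data frame of class `longitudinal_cohort` with those columns.
#' @export
longitudinal_cohort <- function(subject, m1, m2, interval) {
  m1 <- as.numeric(m1); m2 <- as.numeric(m2); interval <- as.numeric(interval)
  n <- length(m1)
  if (length(subject) != n || length(m2) != n || length(interval) != n)
    stop("subject, m1, m2 and interval must have equal length")
  if (any(!is.finite(m1)) || any(!is.finite(m2)))
    stop("measurements must be finite")
  if (any(!is.finite(interval)) || any(interval <= 0))
    stop("interval must be > 0 years")
  structure(data.frame(subject = as.character(subject), m1 = m1, m2 = m2,
                       interval = interval),
            class = c("longitudinal_cohort", "data.frame"))
}

#' Read a visit-pair table (columns subject,m1,m2,interval_years)
#' @param path CSV path.
#' @return A [longitudinal_cohort()].
#' @export
read_longitudinal_table <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path)
  tab <- utils::read.csv(path)
  need <- c("subject", "m1", "m2", "interval_years")
  if (!all(need %in% names(tab)))
    stop("visit table must have columns ", paste(need, collapse = ","))
  longitudinal_cohort(tab$subject, tab$m1, tab$m2, tab$interval_years)
}

#' Visit-pair change metrics and effect size
#'
#' Per subject: delta = m2 - m1; delta% = 100 * delta / m1; annual rate =
#' delta / interval. The summary reports mean and SD of each and Cohen's
#' d for the longitudinal change, defined as mean(rate) / sd(rate). A
#' degenerate cohort with zero rate SD is reported as d = 0 with
#' `degenerate = TRUE` rather than an error, so cohort sweeps do not
#' abort.
#'
#' @param records A [longitudinal_cohort()] (n >= 2).
#' @return An object of class `change_summary`: per-subject vectors
#'   `delta`, `delta_pct`, `rate`, the paired t-test of m2 vs m1
#'   (`paired_t`, `paired_p`), summary means/SDs, and `effect_size_d`.
#' @export
change_metrics <- function(records) {
  n <- nrow(records)
  if (n < 2L)
    stop("need n >= 2 subjects")
  if (any(records$m1 <= 0))
    stop("m1 must be > 0 for percent change")
  delta <- records$m2 - records$m1
  delta_pct <- 100 * delta / records$m1
  rate <- delta / records$interval
  # zero-variance nonzero change (identical subjects) yields an unbounded
  # paired t; report it as +/-Inf with p = 0 instead of aborting the sweep
  pt <- if (stats::sd(delta) == 0 && mean(delta) != 0)
    list(t = sign(mean(delta)) * Inf, p = 0)
  else paired_test(records$m1, records$m2)
  sd_rate <- stats::sd(rate)
  degenerate <- sd_rate == 0
  d <- if (degenerate) 0 else mean(rate) / sd_rate
  structure(list(
    n = n, delta = delta, delta_pct = delta_pct, rate = rate,
    mean_delta = mean(delta), sd_delta = stats::sd(delta),
    mean_delta_pct = mean(delta_pct), sd_delta_pct = stats::sd(delta_pct),
    mean_rate = mean(rate), sd_rate = sd_rate,
    paired_t = pt$t, paired_p = pt$p,
    effect_size_d = d, degenerate = degenerate),
    class = "change_summary")
}

#' @export
print.change_summary <- function(x, ...) {
  cat(sprintf("Longitudinal change summary (n = %d)\n", x$n))
  cat(sprintf("  delta  : %.4f +/- %.4f\n", x$mean_delta, x$sd_delta))
  cat(sprintf("  delta%% : %.2f +/- %.2f\n", x$mean_delta_pct, x$sd_delta_pct))
  cat(sprintf("  rate   : %.4f +/- %.4f per year\n", x$mean_rate, x$sd_rate))
  cat(sprintf("  paired t = %.3f, p = %.3g\n", x$paired_t, x$paired_p))
  cat(sprintf("  Cohen's d (rate) = %.3f%s\n", x$effect_size_d,
              if (x$degenerate) " [degenerate: zero rate SD]" else ""))
  invisible(x)
}

#' Paired t-test of follow-up versus baseline
#'
#' One-sample t-test on the paired differences. Equal vectors (all
#' differences zero) are reported as t = 0, p = 1; zero-variance nonzero
#' differences are an error (t unbounded).
#'
#' @param baseline,followup Numeric vectors of equal length >= 2.
#' @return List with `t` and two-sided `p`.
#' @export
paired_test <- function(baseline, followup) {
  if (length(baseline) != length(followup))
    stop("length mismatch between baseline and follow-up")
  if (length(baseline) < 2L)
    stop("need n >= 2 pairs")
  d <- followup - baseline
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t = 0, p = 1))
    stop("zero-variance nonzero differences: t is unbounded")
  }
  fit <- stats::t.test(followup, baseline, paired = TRUE)
  list(t = unname(fit$statistic), p = fit$p.value)
}

#' Test-retest variability percentage
#'
#' `TRT% = (|M1 - M2| / M1) * 100` per visit pair; applied to a stable
#' (non-accumulating) cohort it measures measurement reproducibility.
#'
#' @param m1 Baseline measurement(s), > 0.
#' @param m2 Follow-up measurement(s).
#' @return TRT% value(s). For a cohort, summarize with mean and SD.
#' @export
trt_percent <- function(m1, m2) {
  if (any(m1 <= 0))
    stop("m1 must be > 0")
  abs(m1 - m2) / m1 * 100
}

#' Trial design for sample-size estimation
#'
#' @param alpha Two-tailed type-I error level (default 0.05).
#' @param power Target power (default 0.80).
#' @param reduction Fraction of the accumulation rate removed by treatment
#'   (0.25 or 0.50 are the conventional scenarios).
#' @param duration Trial duration in years (default 1; descriptive -- the
#'   outcome is the annual rate, so duration cancels out of the test).
#' @param design `"two_sample"` (placebo-controlled, equal arms; default)
#'   or `"one_sample"`.
#' @return An object of class `power_spec`.
#' @export
power_spec <- function(alpha = 0.05, power = 0.80, reduction = 0.25,
                       duration = 1, design = c("two_sample", "one_sample")) {
  design <- match.arg(design)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (!(power > 0 && power < 1)) stop("power must be in (0, 1)")
  if (!(reduction > 0 && reduction <= 1))
    stop("reduction must be in (0, 1]")
  if (!(duration > 0)) stop("duration must be > 0")
  structure(list(alpha = alpha, power = power, reduction = reduction,
                 duration = duration, design = design),
            class = "power_spec")
}

# Exact power of a two-tailed t-test at per-arm (or single-group) size n,
# via the noncentral t distribution.
.t_test_power <- function(n, delta, sd, alpha, design) {
  if (design == "two_sample") {
    df <- 2 * n - 2
    ncp <- delta / (sd * sqrt(2 / n))
  } else {
    df <- n - 1
    ncp <- delta / (sd / sqrt(n))
  }
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tcrit, df, ncp = ncp)
}

#' Per-arm sample size to detect a treatment-reduced accumulation rate
#'
#' Finds the smallest integer n per arm such that a two-tailed t-test at
#' level `alpha`, comparing a treated arm with mean rate
#' `(1 - reduction) * mean_rate` against placebo with mean `mean_rate`
#' (common SD `sd_rate`), achieves at least the target power. Power is
#' computed exactly from the noncentral t distribution and iterated over
#' n.
#'
#' @param mean_rate Observed mean annual rate of change (nonzero).
#' @param sd_rate SD of the annual rate across subjects, > 0.
#' @param spec A [power_spec()].
#' @return Integer n per arm.
#' @export
sample_size_per_arm <- function(mean_rate, sd_rate, spec = power_spec()) {
  if (!is.finite(mean_rate) || mean_rate == 0)
    stop("zero mean rate: required sample size is unbounded")
  if (!is.finite(sd_rate) || sd_rate <= 0)
    stop("sd_rate must be > 0")
  delta <- abs(mean_rate) * spec$reduction
  # z-approximation start, then walk to the smallest adequate n
  z <- stats::qnorm(1 - spec$alpha / 2) + stats::qnorm(spec$power)
  mult <- if (spec$design == "two_sample") 2 else 1
  n <- max(2L, floor(mult * (z * sd_rate / delta)^2) - 2L)
  while (.t_test_power(n, delta, sd_rate, spec$alpha, spec$design) <
         spec$power) {
    n <- n + 1L
    if (n > 1e8L)
      stop("required sample size exceeds 1e8; rate too small relative to SD")
  }
  while (n > 2L &&
         .t_test_power(n - 1L, delta, sd_rate, spec$alpha, spec$design) >=
         spec$power) {
    n <- n - 1L
  }
  as.integer(n)
}

#' Agreement between two sets of longitudinal changes
#'
#' Pearson product-moment correlation with its t-based two-sided p-value,
#' used to ask whether change measured under two reference-region schemes
#' tells the same story.
#'
#' @param changes_a,changes_b Numeric vectors of equal length >= 3.
#' @return List with `r` and `p`.
#' @export
agreement_correlation <- function(changes_a, changes_b) {
  if (length(changes_a) != length(changes_b))
    stop("length mismatch")
  if (length(changes_a) < 3L)
    stop("need n >= 3 pairs")
  if (stats::sd(changes_a) == 0 || stats::sd(changes_b) == 0)
    stop("zero variance: correlation undefined")
  fit <- stats::cor.test(changes_a, changes_b, method = "pearson")
  list(r = unname(fit$estimate), p = fit$p.value)
}
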