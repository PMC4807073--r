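test_that("change metrics follow their definitions", {
  cohort <- longitudinal_cohort(c("a", "b"), c(1.0, 1.0), c(1.1, 1.1),
                                c(2, 2))
  cs <- change_metrics(cohort)
  expect_equal(cs$delta, c(0.1, 0.1))
  expect_equal(cs$delta_pct, c(10, 10))
  expect_equal(cs$rate, c(0.05, 0.05))
})

test_that("a zero-change cohort is degenerate, flagged, not fatal", {
  cohort <- longitudinal_cohort(letters[1:4], rep(1.2, 4), rep(1.2, 4),
                                rep(1, 4))
  cs <- change_metrics(cohort)
  expect_equal(cs$effect_size_d, 0)
  expect_true(cs$degenerate)
  expect_equal(cs$paired_t, 0)
  expect_equal(cs$paired_p, 1)
})

test_that("cohort summaries match a brute-force recomputation", {
  set.seed(19)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    m1 <- stats::rlnorm(n, 0, 0.2) + 0.5
    m2 <- m1 + stats::rnorm(n, 0.05, 0.1)
    interval <- stats::runif(n, 0.8, 3.3)
    cs <- change_metrics(longitudinal_cohort(seq_len(n), m1, m2, interval))
    orc <- oracle_change_summary(m1, m2, interval)
    expect_equal(cs$mean_delta, orc$mean_delta, tolerance = 1e-12)
    expect_equal(cs$sd_delta, orc$sd_delta, tolerance = 1e-12)
    expect_equal(cs$mean_rate, orc$mean_rate, tolerance = 1e-12)
    expect_equal(cs$sd_rate, orc$sd_rate, tolerance = 1e-12)
    expect_equal(cs$mean_delta_pct, orc$mean_delta_pct, tolerance = 1e-12)
    expect_equal(cs$effect_size_d, orc$effect_size_d, tolerance = 1e-12)
  }
  expect_error(change_metrics(longitudinal_cohort("a", 1, 1.1, 1)), "n >= 2")
  expect_error(change_metrics(longitudinal_cohort(c("a", "b"), c(-1, 1),
                                                  c(1, 1.1), c(1, 1))),
               "m1 must be > 0")
})

test_that("change metrics are shift- and scale-equivariant", {
  set.seed(29)
  m1 <- stats::rlnorm(10) + 0.5
  m2 <- m1 + stats::rnorm(10, 0.1, 0.05)
  interval <- stats::runif(10, 1, 3)
  base <- change_metrics(longitudinal_cohort(1:10, m1, m2, interval))
  shift <- change_metrics(longitudinal_cohort(1:10, m1 + 5, m2 + 5, interval))
  expect_equal(shift$delta, base$delta, tolerance = 1e-12)
  scaled <- change_metrics(longitudinal_cohort(1:10, 2 * m1, 2 * m2, interval))
  expect_equal(scaled$delta, 2 * base$delta, tolerance = 1e-12)
  expect_equal(scaled$rate, 2 * base$rate, tolerance = 1e-12)
  expect_equal(scaled$delta_pct, base$delta_pct, tolerance = 1e-12)
  expect_equal(trt_percent(2 * m1, 2 * m2), trt_percent(m1, m2),
               tolerance = 1e-12)
})

test_that("paired test matches mean(d) / (sd(d)/sqrt(n))", {
  b <- c(1, 2, 3, 4.5); f <- b
  expect_equal(paired_test(b, f), list(t = 0, p = 1))
  expect_error(paired_test(b, b + 1), "unbounded")
  expect_error(paired_test(b, f[1:3]), "length mismatch")
  set.seed(37)
  for (i in 1:50) {
    n <- sample(2:30, 1)
    b <- stats::rnorm(n); f <- b + stats::rnorm(n, 0.1)
    res <- paired_test(b, f)
    orc <- oracle_paired_t(b, f)
    expect_equal(res$t, orc$t, tolerance = 1e-10)
    expect_equal(res$p, orc$p, tolerance = 1e-10)
  }
})

test_that("TRT% follows its printed formula exactly", {
  expect_equal(trt_percent(2.0, 1.8), 10.0, tolerance = 1e-12)
  expect_equal(trt_percent(1.3, 1.3), 0)
  expect_equal(trt_percent(1.5, 3.0), 100)
  expect_error(trt_percent(0, 1), "m1 must be > 0")
  expect_equal(trt_percent(c(2, 4), c(1.8, 5)), c(10, 25))
})

test_that("sample size matches the z-approximation and power.t.test", {
  n50 <- sample_size_per_arm(0.04, 0.04, power_spec(reduction = 0.5))
  z <- stats::qnorm(0.975) + stats::qnorm(0.8)
  n_z <- 2 * (z * 0.04 / 0.02)^2          # ~62.8 before t-correction
  expect_lte(abs(n50 - n_z), 2)
  # independent route: stats::power.t.test solves the same design
  n_ref <- ceiling(stats::power.t.test(delta = 0.02, sd = 0.04,
                                       sig.level = 0.05, power = 0.8)$n)
  expect_equal(n50, n_ref)
  n_one <- sample_size_per_arm(0.04, 0.04,
                               power_spec(reduction = 0.5,
                                          design = "one_sample"))
  n_one_ref <- ceiling(stats::power.t.test(delta = 0.02, sd = 0.04,
                                           sig.level = 0.05, power = 0.8,
                                           type = "one.sample")$n)
  expect_equal(n_one, n_one_ref)
})

test_that("sample size scales quadratically in sd over effect", {
  n50 <- sample_size_per_arm(0.04, 0.04, power_spec(reduction = 0.5))
  n25 <- sample_size_per_arm(0.04, 0.04, power_spec(reduction = 0.25))
  expect_gte(n25 / n50, 3.8)
  expect_lte(n25 / n50, 4.2)
  n_sd2 <- sample_size_per_arm(0.04, 0.08, power_spec(reduction = 0.5))
  expect_lte(abs(n_sd2 - 4 * n50) / (4 * n50), 0.05)
})

test_that("sample size is monotone in rate, reduction, sd and power", {
  spec <- power_spec(reduction = 0.5)
  expect_lte(sample_size_per_arm(0.08, 0.04, spec),
             sample_size_per_arm(0.04, 0.04, spec))
  expect_lte(sample_size_per_arm(-0.08, 0.04, spec),
             sample_size_per_arm(0.04, 0.04, spec))  # sign-free
  expect_lte(sample_size_per_arm(0.04, 0.04, power_spec(reduction = 0.5)),
             sample_size_per_arm(0.04, 0.04, power_spec(reduction = 0.25)))
  expect_lte(sample_size_per_arm(0.04, 0.02, spec),
             sample_size_per_arm(0.04, 0.04, spec))
  expect_lte(sample_size_per_arm(0.04, 0.04, spec),
             sample_size_per_arm(0.04, 0.04,
                                 power_spec(reduction = 0.5, power = 0.9)))
  expect_error(sample_size_per_arm(0, 0.04, spec), "unbounded")
  expect_error(sample_size_per_arm(0.04, 0, spec), "sd_rate")
})

test_that("returned n achieves the target power and n-1 does not", {
  spec <- power_spec(reduction = 0.5)
  n <- sample_size_per_arm(0.04, 0.04, spec)
  pw <- function(m) stats::pt(stats::qt(0.975, 2 * m - 2), 2 * m - 2,
                              ncp = 0.02 / (0.04 * sqrt(2 / m)),
                              lower.tail = FALSE) +
    stats::pt(-stats::qt(0.975, 2 * m - 2), 2 * m - 2,
              ncp = 0.02 / (0.04 * sqrt(2 / m)))
  expect_gte(pw(n), 0.8)
  expect_lt(pw(n - 1), 0.8)
})

test_that("agreement correlation matches the covariance formula", {
  a <- c(1, 2, 3, 5, 8)
  expect_equal(agreement_correlation(a, a)$r, 1)
  expect_equal(agreement_correlation(a, -a)$r, -1)
  expect_error(agreement_correlation(a, a[1:3]), "length mismatch")
  expect_error(agreement_correlation(a[1:2], a[1:2]), "n >= 3")
  expect_error(agreement_correlation(a, rep(1, 5)), "zero variance")
  set.seed(41)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    x <- stats::rnorm(n); y <- 0.6 * x + stats::rnorm(n)
    res <- agreement_correlation(x, y)
    orc <- oracle_pearson(x, y)
    expect_equal(res$r, orc$r, tolerance = 1e-10)
    expect_equal(res$p, orc$p, tolerance = 1e-10)
  }
})
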