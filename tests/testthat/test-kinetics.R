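test_that("cumulative_integral matches trapezoid closed forms", {
  t <- c(1, 2, 4, 8, 16)
  # constant TAC: exact c*t beyond the initial (0,0)-anchored ramp, which
  # contributes c*t1/2
  const <- tac(t, rep(1, 5), rep(3, 5))
  expect_equal(cumulative_integral(const), 3 * t - 3 * t[1] / 2)
  linear <- tac(t, rep(1, 5), t)
  expect_equal(cumulative_integral(linear), t^2 / 2)
  zero <- tac(t, rep(1, 5), rep(0, 5))
  expect_equal(cumulative_integral(zero), rep(0, 5))
  # non-decreasing for non-negative TACs
  set.seed(3)
  rnd <- tac(t, rep(1, 5), stats::runif(5))
  expect_true(all(diff(cumulative_integral(rnd)) >= 0))
})

test_that("proportional curves give exact slopes with r^2 = 1", {
  sched <- default_frame_schedule()
  base <- tac_on_schedule(sched, 5 + frame_mid_times(sched) * 0.1)
  for (a in c(0.5, 1, 2)) {
    target <- tac_on_schedule(sched, a * base$values)
    fit <- logan_reference(target, base)
    expect_equal(fit$slope, a, tolerance = 1e-12)
    expect_equal(fit$bp_nd, a - 1, tolerance = 1e-12)
    expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  }
  ident <- logan_reference(base, base)
  expect_equal(ident$slope, 1, tolerance = 1e-12)
  expect_equal(ident$bp_nd, 0, tolerance = 1e-12)
})

test_that("reference Logan recovers DVR on noise-free one-tissue kinetics", {
  sched <- default_frame_schedule()
  input <- simulate_input_function()
  ref <- simulate_tissue_tac(compartment_spec("one_tissue", 0.2, 0.2),
                             input, sched)
  tgt <- simulate_tissue_tac(compartment_spec("one_tissue", 0.2, 0.1),
                             input, sched)
  fit <- logan_reference(tgt, ref, tstar = 30)
  expect_equal(fit$slope, 2, tolerance = 0.02)
  expect_equal(fit$n_points, sum(frame_mid_times(sched) >= 30))
  expect_gt(fit$r_squared, 0.999)
  # with the full ordinate (known reference k2') accuracy does not degrade
  fit_k2 <- logan_reference(tgt, ref, tstar = 30, k2prime = 0.2)
  expect_equal(fit_k2$slope, 2, tolerance = 0.02)
})

test_that("late-window DVR error shrinks with tstar where bias dominates", {
  sched <- default_frame_schedule()
  input <- simulate_input_function()
  ref <- simulate_tissue_tac(compartment_spec("one_tissue", 0.2, 0.2),
                             input, sched)
  tgt <- simulate_tissue_tac(compartment_spec("one_tissue", 0.2, 0.2 / 3),
                             input, sched)
  errs <- vapply(c(20, 30, 40), function(ts)
    abs(logan_reference(tgt, ref, tstar = ts)$slope - 3) / 3, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("plasma Logan recovers V_T and scales with the target", {
  sched <- default_frame_schedule()
  input <- simulate_input_function()
  tgt <- simulate_tissue_tac(compartment_spec("one_tissue", 0.1, 0.05),
                             input, sched)
  fit <- logan_plasma(tgt, input, tstar = 30)
  expect_equal(fit$slope, 2, tolerance = 0.02)
  scaled <- tac_on_schedule(sched, 3 * tgt$values)
  expect_equal(logan_plasma(scaled, input, 30)$slope, 3 * fit$slope,
               tolerance = 1e-9)
  # proportional plasma curve: exact slope
  prop_input <- input_function(frame_mid_times(sched),
                               (5 + frame_mid_times(sched) * 0.1) / 2)
  prop <- tac_on_schedule(sched, 2 * prop_input$total_plasma)
  pfit <- logan_plasma(prop, prop_input)
  expect_equal(pfit$slope, 2, tolerance = 1e-12)
  expect_equal(pfit$r_squared, 1, tolerance = 1e-12)
})

test_that("reference DVR equals the plasma V_T ratio on simulations", {
  sched <- default_frame_schedule()
  input <- simulate_input_function()
  ref <- simulate_tissue_tac(compartment_spec("one_tissue", 0.2, 0.2),
                             input, sched)
  vt_ref <- logan_plasma(ref, input, 30)$slope
  for (dvr_true in c(1.5, 2)) {
    tgt <- simulate_tissue_tac(
      compartment_spec("one_tissue", 0.2, 0.2 / dvr_true), input, sched)
    dvr <- logan_reference(tgt, ref, 30)$slope
    vt_tgt <- logan_plasma(tgt, input, 30)$slope
    expect_equal(dvr, vt_tgt / vt_ref, tolerance = 0.02)
  }
})

test_that("Logan fits are invariant to common positive rescaling", {
  sched <- default_frame_schedule()
  input <- simulate_input_function()
  ref <- simulate_tissue_tac(compartment_spec("one_tissue", 0.2, 0.2),
                             input, sched)
  tgt <- simulate_tissue_tac(compartment_spec("one_tissue", 0.2, 0.1),
                             input, sched)
  base <- logan_reference(tgt, ref)
  set.seed(17)
  for (a in stats::rlnorm(5)) {
    fit <- logan_reference(tac_on_schedule(sched, a * tgt$values),
                           tac_on_schedule(sched, a * ref$values))
    expect_equal(fit$slope, base$slope, tolerance = 1e-10)
  }
})

test_that("Logan pre-conditions are enforced", {
  sched <- default_frame_schedule()
  base <- tac_on_schedule(sched, 5 + frame_mid_times(sched) * 0.1)
  expect_error(logan_reference(base, base, tstar = 69), ">= 3 frames")
  neg <- tac_on_schedule(sched, rep(-1, n_frames(sched)))
  expect_error(logan_reference(neg, base, 30), "positive")
  short_ref <- tac(c(40, 50, 60), rep(5, 3), rep(1, 3))
  expect_error(logan_reference(base, short_ref), "frame grid")
  trunc_input <- input_function(seq(0, 20, 0.5),
                                rep(1, length(seq(0, 20, 0.5))))
  expect_error(logan_plasma(base, trunc_input), "does not cover")
})

test_that("parent-fraction correction is an exact pointwise product", {
  times <- c(0, 1, 2, 5, 10)
  inp <- input_function(times, c(0, 10, 8, 4, 2), c(1, 0.5, 1, 0.25, 1))
  corr <- apply_parent_fraction(inp)
  expect_equal(corr$total_plasma, c(0, 5, 8, 1, 2))
  expect_true(all(corr$parent_fraction == 1))
  ident <- input_function(times, c(0, 10, 8, 4, 2))
  expect_equal(apply_parent_fraction(ident)$total_plasma,
               ident$total_plasma)
  zero <- input_function(times, c(0, 10, 8, 4, 2), rep(0, 5))
  expect_equal(apply_parent_fraction(zero)$total_plasma, rep(0, 5))
  # uncorrected input is refused by the plasma fit
  sched <- default_frame_schedule()
  base <- tac_on_schedule(sched, 5 + frame_mid_times(sched) * 0.1)
  pending <- input_function(seq(0, 70, 0.5), rep(1, 141),
                            rep(0.5, 141))
  expect_error(logan_plasma(base, pending), "parent fraction")
})

test_that("logan_fit methods expose the fitted line", {
  sched <- default_frame_schedule()
  base <- tac_on_schedule(sched, 5 + frame_mid_times(sched) * 0.1)
  target <- tac_on_schedule(sched, 2 * base$values)
  fit <- logan_reference(target, base)
  expect_equal(unname(coef(fit)), c(fit$slope, fit$intercept))
  expect_equal(predict(fit), fit$y, tolerance = 1e-9)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-9)
  expect_output(print(fit), "DVR")
})
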