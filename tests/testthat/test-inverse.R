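# LTI convolution prediction and the double-loop inverse estimator

test_that("convolving a unit-area pulse reproduces the LDRW curve", {
  th <- ldrw_params(0.02, 300, 2)
  dt <- 10
  tt <- seq(0, 3000, by = dt)
  # triangular pulse centred on an interior grid node (trapezoidal area 1);
  # the response is the kernel delayed by the pulse centre
  blood <- concentration_series(c(0, dt, 2 * dt, 3000),
                                c(0, 1 / dt, 0, 0), "blood")
  pred <- predict_sweat(th, blood, tt, dt_conv = dt, pre_history = "zero")
  ref <- ldrw_evaluate(th, pmax(tt - dt, 0))
  i <- ref > 0.05 * max(ref)
  expect_lt(max(abs(pred$values[i] - ref[i]) / max(ref)), 0.01)
})

test_that("constant blood tends to the DC gain A times the input", {
  th <- ldrw_params(0.02, 300, 2)
  blood <- concentration_series(0, 5.5, "blood")
  out <- predict_sweat(th, blood, c(4000, 5000), pre_history = "zero")
  expect_equal(tail(out$values, 1), th$A * 5.5, tolerance = 0.01)
  # with steady pre-history the identity is exact at every time
  out2 <- predict_sweat(th, blood, c(0, 100, 2000))
  expect_equal(out2$values, rep(th$A * 5.5, 3), tolerance = 1e-9)
})

test_that("prediction is linear in the blood input", {
  th <- ldrw_params(0.02, 300, 2)
  tt <- seq(0, 3000, by = 300)
  b1 <- concentration_series(tt, 5 + sin(tt / 500), "blood")
  b2 <- concentration_series(tt, 4 + cos(tt / 700), "blood")
  badd <- concentration_series(tt, b1$values + b2$values, "blood")
  p1 <- predict_sweat(th, b1, tt)$values
  p2 <- predict_sweat(th, b2, tt)$values
  pa <- predict_sweat(th, badd, tt)$values
  expect_equal(pa, p1 + p2, tolerance = 1e-9)
})

test_that("loop error is the normalised mean-square mismatch", {
  m <- concentration_series(c(0, 60), c(100, 100) * 1e-3, "sweat")
  p <- concentration_series(c(0, 60), c(90, 110) * 1e-3, "sweat")
  expect_equal(loop_error(p, m), 0.01, tolerance = 1e-12)
  expect_equal(loop_error(m, m), 0)
  m2 <- concentration_series(m$times, m$values * 7.3, "sweat")
  p2 <- concentration_series(p$times, p$values * 7.3, "sweat")
  expect_equal(loop_error(p2, m2), loop_error(p, m), tolerance = 1e-12)
})

test_that("defaults match the published double-loop configuration", {
  o <- inverse_options(baseline_theta0)
  expect_equal(o$c_blood_init, 5.5)
  expect_equal(o$error_tol, 0.001)
  expect_equal(o$mode, "sequential")
  expect_error(inverse_options(ldrw_params(5, 100, 1)), "theta_bounds")
})

test_that("a constant-blood fixed point is recovered and flagged converged", {
  th <- baseline_theta0
  tt <- seq(0, 3300, by = 300)
  sweat <- predict_sweat(th, concentration_series(0, 5.5, "blood"), tt)
  res <- estimate_blood(sweat, inverse_options(th))
  expect_true(res$converged)
  expect_lt(max(abs(res$blood_est$values - 5.5)) / 5.5, 0.01)
})

test_that("noise-free synthetic meal data are recovered accurately", {
  pd <- generate_paired(meal_spec(21), "ldrw")
  res <- estimate_blood(pd$sweat_obs,
                        inverse_options(pd$generator_trace$theta_effective))
  expect_true(res$converged)
  expect_gte(cor(res$blood_est$values, pd$blood_true$values), 0.95)
  expect_lt(rel_rmse(res$blood_est$values, pd$blood_true$values), 0.05)
})

test_that("the error trace is non-increasing and bounds are respected", {
  pd <- generate_paired(meal_spec(5, noise = 0.05), "ldrw")
  opts <- inverse_options(pd$generator_trace$theta_effective, mode = "batch")
  res <- estimate_blood(pd$sweat_obs, opts)
  expect_true(length(res$error_trace) >= 1)
  expect_true(all(diff(res$error_trace) <= 1e-12))
  expect_true(all(res$blood_est$values >= opts$blood_bounds[1] &
                    res$blood_est$values <= opts$blood_bounds[2]))
  th <- res$theta_final
  expect_true(th$A >= opts$theta_bounds$A[1] && th$A <= opts$theta_bounds$A[2])
  expect_true(th$mu >= opts$theta_bounds$mu[1] && th$mu <= opts$theta_bounds$mu[2])
  expect_true(th$lam >= opts$theta_bounds$lam[1] && th$lam <= opts$theta_bounds$lam[2])
})

test_that("estimation is bitwise deterministic", {
  pd <- generate_paired(meal_spec(9, noise = 0.05), "ldrw")
  opts <- inverse_options(pd$generator_trace$theta_effective)
  r1 <- estimate_blood(pd$sweat_obs, opts)
  r2 <- estimate_blood(pd$sweat_obs, opts)
  expect_identical(r1$error_trace, r2$error_trace)
  expect_identical(r1$blood_est$values, r2$blood_est$values)
})

test_that("a single measurement degenerates to the static-gain estimate", {
  th <- baseline_theta0
  sweat <- concentration_series(0, th$A * 7.2, "sweat")
  res <- estimate_blood(sweat, inverse_options(th))
  expect_equal(res$blood_est$values, 7.2, tolerance = 1e-9)
})

test_that("non-positive sweat measurements are rejected", {
  z <- concentration_series(c(0, 300), c(0, 0.1), "sweat")
  expect_error(estimate_blood(z, inverse_options(baseline_theta0)),
               "strictly positive")
})
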