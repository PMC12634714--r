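# LDRW curve model: closed forms, moments, log-domain regression fit

test_that("closed-form values of the LDRW curve hold", {
  th111 <- ldrw_params(1, 1, 1)
  expect_equal(ldrw_evaluate(th111, 1), 1 / sqrt(2 * pi), tolerance = 1e-12)
  expect_equal(ldrw_evaluate(th111, 0), 0)
  expect_equal(ldrw_evaluate(th111, 1e-9), 0, tolerance = 1e-15)
  # C(mu) = (A/mu) sqrt(lambda / 2 pi) for arbitrary parameters
  th <- ldrw_params(0.37, 42, 2.5)
  expect_equal(ldrw_evaluate(th, th$mu),
               th$A / th$mu * sqrt(th$lam / (2 * pi)), tolerance = 1e-12)
  expect_equal(ldrw_evaluate(ldrw_params(2, 1, 1), c(0.5, 1, 2)),
               2 * ldrw_evaluate(th111, c(0.5, 1, 2)), tolerance = 1e-12)
  expect_error(ldrw_params(-1, 1, 1), "positive")
  expect_error(ldrw_evaluate(th111, -1), "non-negative")
})

test_that("curve area equals A over a parameter sweep (quadrature oracle)", {
  sweep <- ldrw_sweep(50)
  for (i in seq_len(nrow(sweep))) {
    th <- ldrw_params(sweep$A[i], sweep$mu[i], sweep$lam[i])
    area <- stats::integrate(function(t) ldrw_evaluate(th, t), 0, Inf,
                             rel.tol = 1e-9)$value
    expect_equal(area, th$A, tolerance = 1e-6)
  }
})

test_that("analytic moments agree with quadrature", {
  th <- ldrw_params(1, 1, 1)
  m <- ldrw_moments(th)
  expect_equal(m$area, 1)
  expect_equal(m$mean_transit_time, 2.0)
  expect_equal(m$peak_time, (sqrt(5) - 1) / 2, tolerance = 1e-12)
  for (pars in list(c(0.5, 30, 0.7), c(2, 200, 8))) {
    th <- ldrw_params(pars[1], pars[2], pars[3])
    m <- ldrw_moments(th)
    first_moment <- stats::integrate(function(t) t * ldrw_evaluate(th, t),
                                     0, Inf, rel.tol = 1e-10)$value / th$A
    expect_equal(m$mean_transit_time, first_moment, tolerance = 1e-6)
    # peak time is the argmax
    tt <- seq(m$peak_time * 0.5, m$peak_time * 1.5, length.out = 4001)
    expect_equal(tt[which.max(ldrw_evaluate(th, tt))], m$peak_time,
                 tolerance = 1e-3)
  }
})

test_that("curve rises before the peak and falls after it", {
  th <- ldrw_params(1, 60, 3)
  pk <- ldrw_moments(th)$peak_time
  tt_pre <- seq(pk / 50, pk * 0.99, length.out = 100)
  tt_post <- seq(pk * 1.01, pk * 20, length.out = 100)
  expect_true(all(diff(ldrw_evaluate(th, tt_pre)) > 0))
  expect_true(all(diff(ldrw_evaluate(th, tt_post)) < 0))
})

test_that("larger lambda narrows the normalised curve", {
  variance_of <- function(lam) {
    th <- ldrw_params(1, 60, lam)
    mtt <- ldrw_moments(th)$mean_transit_time
    stats::integrate(function(t) (t - mtt)^2 * ldrw_evaluate(th, t), 0, Inf,
                     rel.tol = 1e-9)$value
  }
  v <- vapply(c(1, 2, 4, 8), variance_of, numeric(1))
  expect_true(all(diff(v) < 0))
})

test_that("log-domain regression recovers parameters exactly from noise-free curves", {
  th <- ldrw_params(0.02, 60, 3)
  tt <- seq(1, 400, length.out = 200)
  fit <- fit_mlr_log(tt, ldrw_evaluate(th, tt))
  expect_true(fit$converged)
  expect_equal(fit$params$A, th$A, tolerance = 1e-6)
  expect_equal(fit$params$mu, th$mu, tolerance = 1e-6)
  expect_equal(fit$params$lam, th$lam, tolerance = 1e-6)
  sweep <- ldrw_sweep(50)
  for (i in seq_len(nrow(sweep))) {
    th <- ldrw_params(sweep$A[i], sweep$mu[i], sweep$lam[i])
    tt <- ldrw_sample_times(th)
    fit <- fit_mlr_log(tt, ldrw_evaluate(th, tt))
    expect_equal(fit$params$A, th$A, tolerance = 1e-6)
    expect_equal(fit$params$mu, th$mu, tolerance = 1e-6)
    expect_equal(fit$params$lam, th$lam, tolerance = 1e-6)
  }
})

test_that("regression slopes equal the analytic linearisation on exact data", {
  th <- ldrw_params(0.5, 120, 4)
  tt <- ldrw_sample_times(th)
  v <- ldrw_evaluate(th, tt)
  keep <- v >= 0.01 * max(v)
  y <- log(v[keep]) + 0.5 * log(tt[keep])
  beta <- coef(lm(y ~ tt[keep] + I(1 / tt[keep])))
  expect_equal(beta[[2]], -th$lam / (2 * th$mu), tolerance = 1e-8)
  expect_equal(beta[[3]], -th$lam * th$mu / 2, tolerance = 1e-8)
})

test_that("fit is robust to multiplicative noise (median over replicates)", {
  th <- ldrw_params(0.02, 60, 3)
  tt <- seq(1, 400, length.out = 200)
  v0 <- ldrw_evaluate(th, tt)
  errs <- withr::with_seed(99, {
    t(replicate(100, {
      v <- v0 * exp(rnorm(length(v0), 0, 0.05))
      f <- fit_mlr_log(tt, v)$params
      abs(c(f$A / th$A, f$mu / th$mu, f$lam / th$lam) - 1)
    }))
  })
  expect_true(all(apply(errs, 2, median) < 0.15))
})

test_that("degenerate fits are rejected", {
  expect_error(fit_mlr_log(1:2, c(1, 2)), "at least 3")
  # monotonically increasing data cannot be LDRW-shaped
  expect_error(fit_mlr_log(1:50, exp(0.1 * (1:50))), "not LDRW-shaped")
})
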