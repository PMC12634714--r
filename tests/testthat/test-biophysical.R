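# forward transport model: flows, dilution, simulation, impulse response

test_that("water-flow arithmetic matches hand computation from the default parameters", {
  fl <- water_flows(default_params)
  expect_equal(fl$Q_water_cap, 3.2175e-16, tolerance = 1e-4)
  expect_equal(fl$R_gland, 2.6076e17, tolerance = 1e-4)
  expect_equal(fl$Q_water_sg, 5.1128e-15, tolerance = 1e-4)
  expect_equal(fl$A_sg, pi * (5e-6)^2 / 4, tolerance = 1e-12)
  expect_equal(fl$u_sg, 2.604e-4, tolerance = 1e-3)
  # same order as the passive sweat velocity
  expect_equal(fl$u_sg_n, fl$u_sg / 3e-4, tolerance = 1e-12)
  expect_true(all(unlist(fl) > 0))
})

test_that("gland flow scales as d^4 in resistance and d^2 in velocity", {
  fl1 <- water_flows(default_params)
  fl2 <- water_flows(update_params(default_params, d = 2 * default_params$d))
  expect_equal(fl2$R_gland, fl1$R_gland / 16, tolerance = 1e-12)
  expect_equal(fl2$u_sg, fl1$u_sg * 4, tolerance = 1e-12)
})

test_that("invalid flow parameters are rejected", {
  expect_error(biophysical_params(d = 0), "positive")
  expect_error(biophysical_params(eta = -1), "positive")
  expect_error(biophysical_params(L = 0), "positive")
  expect_error(biophysical_params(dP = 0), "positive")
  expect_error(biophysical_params(d = 5e-3), "smaller than gland length")
  expect_error(update_params(default_params, bogus = 1), "unknown parameter")
})

test_that("dilution factor follows 1/(1 + K_wg u_sg_n)", {
  expect_equal(dilution_factor(default_params, 0.868), 1 / (1 + 12 * 0.868),
               tolerance = 1e-12)
  expect_equal(dilution_factor(default_params), 0.0876, tolerance = 1e-3)
  expect_equal(dilution_factor(default_params, 0), 1)
  expect_equal(dilution_factor(update_params(default_params, K_wg = 0)), 1)
  expect_error(biophysical_params(K_wg = -1), "non-negative")
  expect_error(dilution_factor(default_params, -0.1), "non-negative")
})

test_that("zero blood input yields identically zero sweat", {
  sw <- simulate_sweat(update_params(default_params, r_uptake = 0),
                       concentration_series(0, 0, "blood"), default_grid)
  expect_true(all(sw$values == 0))
})

test_that("the sink-free system is linear and additive", {
  p0 <- update_params(default_params, r_uptake = 0)
  b1 <- concentration_series(c(0, 900, 3600), c(4, 8, 5), "blood")
  b2 <- concentration_series(c(0, 1800, 3600), c(2, 1, 6), "blood")
  s1 <- simulate_sweat(p0, b1, default_grid)
  s2 <- simulate_sweat(p0, b2, default_grid)
  sdouble <- simulate_sweat(p0, concentration_series(b1$times, 2 * b1$values, "blood"),
                            default_grid)
  expect_equal(sdouble$values, 2 * s1$values, tolerance = 1e-6)
  tt <- sort(unique(c(b1$times, b2$times)))
  badd <- concentration_series(tt,
                               approx(b1$times, b1$values, tt)$y +
                                 approx(b2$times, b2$values, tt)$y, "blood")
  sadd <- simulate_sweat(p0, badd, default_grid)
  expect_equal(sadd$values, s1$values + s2$values, tolerance = 1e-6)
})

test_that("steady step output equals input times impulse-response gain", {
  p0 <- update_params(default_params, r_uptake = 0)
  sw <- simulate_sweat(p0, concentration_series(0, 5.5, "blood"), default_grid)
  expect_equal(tail(sw$values, 1), 5.5 * baseline_h$gain, tolerance = 0.01)
})

test_that("clamped simulation keeps every concentration non-negative", {
  blood <- concentration_series(c(0, 1200, 2400, 3600), c(5, 9, 6, 5.5), "blood")
  sw <- simulate_sweat(default_params, blood, default_grid)
  expect_true(all(sw$values >= 0))
})

test_that("impulse response is causal, non-negative and delta-surrogate converged", {
  expect_true(all(baseline_h$values >= 0))
  expect_equal(baseline_h$values[1], 0)
  expect_equal(baseline_h$gain,
               pracma::trapz(baseline_h$times, baseline_h$values),
               tolerance = 1e-9)
  g_half <- sim_grid(pulse_width = 0.5)
  h_half <- impulse_response(default_params, g_half)
  expect_equal(h_half$gain, baseline_h$gain, tolerance = 0.01)
})

test_that("gain is grid-converged", {
  g2 <- sim_grid(n_isf = 80, n_sg = 320, dt = 0.125)
  h2 <- impulse_response(default_params, g2)
  expect_equal(h2$gain, baseline_h$gain, tolerance = 0.01)
})

test_that("gland segment conserves mass between wall influx and outlet efflux", {
  p <- update_params(default_params, r_uptake = 0, K_wg = 0)
  blood <- concentration_series(c(0, 60, 60.25, 3600), c(1, 1, 0, 0), "blood")
  fx <- sweat2blood:::transport_fluxes(p, blood, default_grid)
  m_in <- pracma::trapz(fx$times, fx$influx)
  m_out <- pracma::trapz(fx$times, fx$outflux)
  expect_gt(m_in, 0)
  expect_equal(m_out, m_in, tolerance = 0.01)
})

test_that("grid and input validation errors are raised", {
  expect_error(sim_grid(n_isf = 5), "n_isf")
  expect_error(sim_grid(dt = 0), "dt")
  expect_error(sim_grid(t_end = 0.5, pulse_width = 1), "t_end")
  short_blood <- concentration_series(c(0, 100), c(5, 5), "blood")
  expect_error(simulate_sweat(default_params, short_blood, default_grid),
               "cover")
  expect_error(impulse_response(default_params, sim_grid(dt = 2, pulse_width = 1)),
               "pulse_width")
})
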