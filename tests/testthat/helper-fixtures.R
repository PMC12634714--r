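# shared fixtures: cheap grids and a cached baseline impulse response / theta

default_params <- biophysical_params()
default_grid <- sim_grid()

# computed once per test run; several files need them
baseline_h <- impulse_response(default_params, default_grid)
baseline_theta0 <- fit_mlr_log(baseline_h$times, baseline_h$values)$params

# Latin-hypercube style parameter sweep over the LDRW parameter box
# A in [1e-3, 1], mu in [1, 1e3], lam in [0.2, 50] (log-uniform strata)
ldrw_sweep <- function(n = 50, seed = 404) {
  withr::with_seed(seed, {
    u <- if (requireNamespace("lhs", quietly = TRUE)) {
      lhs::randomLHS(n, 3)
    } else {
      matrix(stats::runif(3 * n), ncol = 3)
    }
    data.frame(A = 10^(-3 + 3 * u[, 1]),
               mu = 10^(3 * u[, 2]),
               lam = 10^(log10(0.2) + (log10(50) - log10(0.2)) * u[, 3]))
  })
}

# sampling grid that straddles the peak and the tail of a given LDRW curve
ldrw_sample_times <- function(theta, n = 300) {
  mtt <- theta$mu * (1 + 1 / theta$lam)
  seq(mtt / 200, 8 * mtt, length.out = n)
}

meal_spec <- function(seed, noise = 0, n_points = 12) {
  experiment_spec(n_points, 5.6, 0.9, 97.1, 13.6, "meal",
                  noise_rel_sd = noise, seed = seed)
}

rel_rmse <- function(est, truth) sqrt(mean((est - truth)^2)) / mean(truth)
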