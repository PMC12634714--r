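#' Specification of a synthetic paired blood/sweat experiment
#'
#' Describes the marginal summary structure of a paired glucose monitoring
#' experiment: number of samples, target mean and SD of the blood trace
#' (mmol L^-1 = mol m^-3) and of the sweat trace (umol L^-1), the glycaemic
#' profile shape, and the measurement noise level. The seven built-in
#' experiment summaries are available through [builtin_experiments()].
#'
#' @param n_points Number of paired measurements (>= 1).
#' @param blood_mean,blood_sd Target mean and SD of blood glucose (mol m^-3).
#' @param sweat_mean,sweat_sd Target mean and SD of sweat glucose
#'   (umol L^-1, i.e. 1e-3 mol m^-3).
#' @param profile_kind `"fasting"` (baseline with low-amplitude
#'   autocorrelated fluctuation), `"meal"` (baseline plus a post-prandial
#'   excursion bump) or `"ogtt"` (a single large glucose-ingestion
#'   excursion).
#' @param noise_rel_sd Relative SD of the multiplicative log-normal
#'   measurement noise on sweat (default 0.05).
#' @param sample_interval Sampling interval in seconds (default 300 s:
#'   5-minute sampling).
#' @param seed Seed for the profile and noise generators.
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(n_points, blood_mean, blood_sd,
                            sweat_mean, sweat_sd,
                            profile_kind = c("meal", "fasting", "ogtt"),
                            noise_rel_sd = 0.05,
                            sample_interval = 300,
                            seed = 1L) {
  profile_kind <- match.arg(profile_kind)
  if (n_points < 1) stop("`n_points` must be at least 1", call. = FALSE)
  if (blood_mean < 0 || blood_sd < 0 || sweat_mean < 0 || sweat_sd < 0) {
    stop("means and SDs must be non-negative", call. = FALSE)
  }
  if (blood_sd > blood_mean) {
    stop("infeasible profile: blood SD exceeds blood mean", call. = FALSE)
  }
  structure(list(n_points = as.integer(n_points),
                 duration = sample_interval * max(n_points - 1L, 1L),
                 blood_mean = blood_mean, blood_sd = blood_sd,
                 sweat_mean = sweat_mean, sweat_sd = sweat_sd,
                 profile_kind = profile_kind, noise_rel_sd = noise_rel_sd,
                 sample_interval = sample_interval, seed = as.integer(seed)),
            class = "experiment_spec")
}

#' The seven built-in experiment summaries
#'
#' Marginal summaries (sample counts, blood glucose mean +/- SD in
#' mmol L^-1, sweat glucose mean +/- SD in umol L^-1) of seven published
#' paired sweat/blood glucose monitoring experiments, used as generator
#' targets so that every other module can be exercised on realistically
#' scaled data without any external download.
#'
#' @param seed Seed stored in each spec.
#' @return Named list of `experiment_spec` objects (`exp1` ... `exp7`).
#' @export
builtin_experiments <- function(seed = 1L) {
  mk <- function(n, bm, bs, sm, ss, kind, s_off)
    experiment_spec(n, bm, bs, sm, ss, kind, seed = seed + s_off)
  list(
    exp1 = mk(15, 5.6, 0.9, 97.1, 13.6, "meal", 1L),
    exp2 = mk(19, 11.4, 5.7, 37.5, 22.4, "ogtt", 2L),
    exp3 = mk(6, 15.4, 2.1, 178.3, 34.3, "meal", 3L),
    exp4 = mk(7, 5.0, 0.1, 19.3, 12.1, "fasting", 4L),
    exp5 = mk(5, 4.7, 0.6, 42.4, 26.4, "fasting", 5L),
    exp6 = mk(8, 6.4, 1.2, 69.4, 36.3, "meal", 6L),
    exp7 = mk(48, 4.6, 0.6, 12.8, 4.9, "fasting", 7L)
  )
}

# smooth standardised AR(1) fluctuation, zero mean, unit sd
ar1_fluct <- function(n, phi = 0.8) {
  z <- as.numeric(stats::filter(stats::rnorm(n), phi, method = "recursive"))
  if (stats::sd(z) == 0) return(rep(0, n))
  (z - mean(z)) / stats::sd(z)
}

#' Generate a synthetic blood glucose profile
#'
#' Builds a blood glucose time course whose realised sample mean and SD
#' match the spec targets: a gamma-shaped excursion bump
#' `(t/tau) exp(1 - t/tau)` (meal/OGTT, 30-60 minute timescale) or a
#' low-amplitude autocorrelated fluctuation (fasting), affinely rescaled so
#' the realised moments hit the targets, then floored away from zero (the
#' floor is followed by one rescaling pass, so realised moments stay within
#' a few percent of the targets even for high-variability specs).
#' Deterministic under the spec seed.
#'
#' @param spec An `experiment_spec`.
#' @return A `concentration_series` with label `"blood"`.
#' @examples
#' generate_blood_profile(builtin_experiments()$exp1)
#' @export
generate_blood_profile <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  n <- spec$n_points
  times <- seq(0, by = spec$sample_interval, length.out = n)
  if (spec$blood_sd == 0 || n == 1L) {
    return(concentration_series(times, rep(spec$blood_mean, n), "blood"))
  }
  withr::local_seed(spec$seed)
  shape <- switch(spec$profile_kind,
    fasting = ar1_fluct(n),
    meal = {
      t0 <- 0.15 * spec$duration
      tau <- min(2700, max(900, spec$duration / 4))  # 15-45 min rise
      tt <- pmax(times - t0, 0)
      bump <- (tt / tau) * exp(1 - tt / tau)
      bump + 0.15 * ar1_fluct(n)
    },
    ogtt = {
      t0 <- 0.1 * spec$duration
      tau <- min(2400, max(900, spec$duration / 5))
      tt <- pmax(times - t0, 0)
      bump <- (tt / tau) * exp(1 - tt / tau)
      bump + 0.1 * ar1_fluct(n)
    })
  s <- (shape - mean(shape)) / stats::sd(shape)
  v <- spec$blood_mean + spec$blood_sd * s
  floor_v <- 0.05 * spec$blood_mean
  if (any(v < floor_v)) {
    v <- pmax(v, floor_v)
    # one affine re-match pass after flooring
    if (stats::sd(v) > 0) {
      v <- spec$blood_mean + spec$blood_sd * (v - mean(v)) / stats::sd(v)
      v <- pmax(v, floor_v)
    }
  }
  concentration_series(times, v, "blood")
}

#' Generate a paired blood/sweat dataset
#'
#' Produces a ground-truth blood profile and the corresponding observed
#' sweat trace: the forward-model response to the blood profile, rescaled
#' by a gain factor so the realised sweat mean matches the spec target
#' (sweat stimulation and hence the blood-to-sweat gain differed between
#' the underlying experiments), then corrupted with mean-preserving
#' multiplicative log-normal noise of relative SD `noise_rel_sd`.
#'
#' @param spec An `experiment_spec`.
#' @param forward `"ldrw"` (convolution with an LDRW kernel) or
#'   `"biophysical"` (convolution with the transport-model impulse
#'   response).
#' @param theta LDRW kernel parameters; defaults to the fit of the baseline
#'   impulse response.
#' @param params `biophysical_params` for the biophysical forward model.
#' @param grid `sim_grid` used for the impulse response.
#' @param dt_conv Convolution grid step (s).
#' @return An object of class `paired_dataset`: list with `blood_true`,
#'   `sweat_obs` (both `concentration_series`) and `generator_trace`
#'   (spec, forward model, gain factor, and the effective LDRW parameters
#'   `theta_effective` whose gain includes the rescale — the correct
#'   `theta0` for inverting the dataset).
#' @export
generate_paired <- function(spec, forward = c("ldrw", "biophysical"),
                            theta = NULL, params = biophysical_params(),
                            grid = sim_grid(), dt_conv = 10) {
  forward <- match.arg(forward)
  stopifnot(inherits(spec, "experiment_spec"))
  blood_true <- generate_blood_profile(spec)
  times <- blood_true$times

  if (forward == "ldrw") {
    if (is.null(theta)) theta <- baseline_theta(params, grid)
    raw <- predict_sweat(theta, blood_true, times, dt_conv)$values
  } else {
    h <- impulse_response(params, grid)
    grid_t <- seq(0, max(times) + dt_conv, by = dt_conv)
    hg <- stats::approx(h$times, h$values, xout = grid_t, rule = 2)$y
    bg <- interp_series(blood_true, grid_t)
    y <- conv_grid(bg, hg, dt_conv)
    # steady pre-history at the first blood value (numeric kernel area)
    cumH <- as.numeric(pracma::cumtrapz(grid_t, hg))
    y <- y + bg[1] * pmax(h$gain - cumH, 0)
    raw <- stats::approx(grid_t, y, xout = times, rule = 2)$y
    theta <- fit_mlr_log(h$times, h$values)$params
  }
  if (mean(raw) <= 0) stop("forward model produced a non-positive sweat trace", call. = FALSE)
  gamma <- (spec$sweat_mean * 1e-3) / mean(raw)
  sweat <- raw * gamma
  if (spec$noise_rel_sd > 0) {
    withr::local_seed(spec$seed + 5000L)
    s <- spec$noise_rel_sd
    sweat <- sweat * exp(stats::rnorm(length(sweat), 0, s) - s^2 / 2)
  }
  theta_eff <- ldrw_params(theta$A * gamma, theta$mu, theta$lam)
  structure(list(blood_true = blood_true,
                 sweat_obs = concentration_series(times, sweat, "sweat"),
                 generator_trace = list(spec = spec, forward = forward,
                                        gain_rescale = gamma,
                                        theta_forward = theta,
                                        theta_effective = theta_eff)),
            class = "paired_dataset")
}

#' @export
print.paired_dataset <- function(x, ...) {
  tr <- x$generator_trace
  cat(sprintf("<paired_dataset> %d points, forward = %s, gain rescale = %.3g\n",
              nrow(x$blood_true), tr$forward, tr$gain_rescale))
  cat(sprintf("  blood: %.3g +/- %.3g mmol/L; sweat: %.3g +/- %.3g umol/L\n",
              mean(x$blood_true$values), stats::sd(x$blood_true$values),
              1e3 * mean(x$sweat_obs$values), 1e3 * stats::sd(x$sweat_obs$values)))
  invisible(x)
}
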