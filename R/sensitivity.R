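#' Coefficient of variation in percent
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation.
#'
#' @param x Numeric vector with at least 2 values and non-zero mean.
#' @export
cv_percent <- function(x) {
  if (length(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  m <- mean(x)
  if (m == 0) stop("CV undefined: mean is zero", call. = FALSE)
  100 * stats::sd(x) / m
}

#' Specification of a Monte-Carlo sensitivity run
#'
#' @param n_samples Number of Gaussian parameter draws (default 100).
#' @param rel_sd Relative standard deviation of the draws (default 0.10).
#' @param seed Base seed; each (parameter, analysis) pair uses its own
#'   derived stream so results do not depend on execution order.
#' @return An object of class `sensitivity_spec`.
#' @export
sensitivity_spec <- function(n_samples = 100, rel_sd = 0.10, seed = 1L) {
  if (n_samples < 2) stop("`n_samples` must be at least 2", call. = FALSE)
  if (!(rel_sd > 0 && rel_sd < 1)) stop("`rel_sd` must be in (0, 1)", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples), rel_sd = rel_sd,
                 seed = as.integer(seed)),
            class = "sensitivity_spec")
}

BIOPHYS_PARAM_NAMES <- c("P_c", "L_pc", "k_DE", "V_p", "V_ISF", "P_ISF",
                         "D_sg_wall", "D_ISF", "D_sw", "d", "A_ISF", "dP",
                         "K_wg", "L", "h_sg", "A_c", "r_uptake", "eta")
LDRW_PARAM_NAMES <- c("A", "mu", "lam")

# per-(parameter, analysis) seed stream, independent of execution order
param_seed <- function(spec, param_name, analysis) {
  idx <- match(param_name, c(BIOPHYS_PARAM_NAMES, LDRW_PARAM_NAMES))
  (spec$seed + 7919L * analysis + 101L * idx) %% .Machine$integer.max
}

# Gaussian draws around a nominal value; draws whose sign differs from the
# nominal (or that are zero) are redrawn to respect physical sign constraints
gaussian_draws <- function(nominal, n, rel_sd) {
  draws <- stats::rnorm(n, nominal, rel_sd * abs(nominal))
  bad <- draws * sign(nominal) <= 0
  while (any(bad)) {
    draws[bad] <- stats::rnorm(sum(bad), nominal, rel_sd * abs(nominal))
    bad <- draws * sign(nominal) <= 0
  }
  draws
}

# The scalar output statistic of the first sensitivity analysis: the sweat
# glucose concentration reached at the end of the simulation window under a
# constant blood input, obtained from the model's impulse-response
# characterisation (for a constant input this equals the input times the
# trapezoidal area of the impulse curve over the window).
output_stat_biophysical <- function(params, grid, blood_const = 5.5) {
  blood_const * impulse_response(params, grid)$gain
}

output_stat_ldrw <- function(theta, t_end = 3600, dt = 10, blood_const = 5.5) {
  tt <- seq(0, t_end, by = dt)
  blood_const * trapz_area(tt, ldrw_evaluate(theta, tt))
}

# nominal LDRW parameters: fit of the baseline impulse response
baseline_theta <- function(params = biophysical_params(), grid = sim_grid()) {
  h <- impulse_response(params, grid)
  fit_mlr_log(h$times, h$values)$params
}

#' First sensitivity analysis: output CV under parameter perturbation
#'
#' Draws `n_samples` Gaussian values of one model parameter (mean = nominal,
#' SD = `rel_sd` * nominal, sign-preserving redraws), evaluates the simulated
#' sweat glucose output statistic for each draw, and reports the coefficient
#' of variation of the outputs. The output statistic is the sweat
#' concentration at the end of the simulation window under a constant blood
#' input of 5.5 mol m^-3.
#'
#' @param model `"ldrw"` or `"biophysical"`.
#' @param param_name Parameter to perturb: one of `A`, `mu`, `lam` for the
#'   LDRW model, or a biophysical parameter name.
#' @param spec A `sensitivity_spec`.
#' @param params Nominal `biophysical_params` (biophysical model and the
#'   baseline LDRW fit).
#' @param grid `sim_grid` defining the simulation window.
#' @param theta Nominal `ldrw_params`; defaults to the fit of the baseline
#'   impulse response.
#' @return A list of class `sensitivity_result` with `param_name`, `model`,
#'   `cv_output` (percent), `n_effective` and the raw `outputs`.
#' @export
analysis_one <- function(model = c("ldrw", "biophysical"), param_name,
                         spec = sensitivity_spec(),
                         params = biophysical_params(), grid = sim_grid(),
                         theta = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(spec, "sensitivity_spec"))
  valid <- if (model == "ldrw") LDRW_PARAM_NAMES else BIOPHYS_PARAM_NAMES
  if (!param_name %in% valid) {
    stop(sprintf("unknown parameter `%s` for the %s model", param_name, model),
         call. = FALSE)
  }
  withr::local_seed(param_seed(spec, param_name, 1L))
  if (model == "ldrw") {
    if (is.null(theta)) theta <- baseline_theta(params, grid)
    nominal <- theta[[param_name]]
    draws <- gaussian_draws(nominal, spec$n_samples, spec$rel_sd)
    outputs <- vapply(draws, function(v) {
      th <- theta; th[[param_name]] <- v
      output_stat_ldrw(th, t_end = grid$t_end)
    }, numeric(1))
  } else {
    nominal <- params[[param_name]]
    draws <- gaussian_draws(nominal, spec$n_samples, spec$rel_sd)
    outputs <- vapply(draws, function(v) {
      tryCatch({
        repl <- stats::setNames(list(v), param_name)
        p2 <- do.call(update_params, c(list(params), repl))
        output_stat_biophysical(p2, grid)
      }, error = function(e) NA_real_)
    }, numeric(1))
  }
  outputs <- outputs[is.finite(outputs)]
  if (length(outputs) < 2L) stop("all draws invalid", call. = FALSE)
  structure(list(param_name = param_name, model = model,
                 cv_output = cv_percent(outputs),
                 n_effective = length(outputs), outputs = outputs),
            class = "sensitivity_result")
}

#' Second sensitivity analysis: LDRW parameter CVs under biophysical
#' perturbation
#'
#' For each Gaussian draw of one biophysical parameter, recomputes the
#' impulse response of the transport model, refits the LDRW curve by the
#' log-domain regression, and reports the coefficients of variation of the
#' refitted `A`, `mu` and `lam` across draws. Draws on which the fit fails
#' are dropped (`n_effective` decremented); a `warn` flag is set if more
#' than 20 percent are dropped.
#'
#' @inheritParams analysis_one
#' @param param_name A biophysical parameter name (normally one whose
#'   analysis-1 CV exceeds 0.1 percent).
#' @return A list of class `sensitivity_result` with `cv_A`, `cv_mu`,
#'   `cv_lam` (percent), `n_effective`, `warn` and the per-draw fits.
#' @export
analysis_two <- function(param_name, spec = sensitivity_spec(),
                         params = biophysical_params(), grid = sim_grid()) {
  stopifnot(inherits(spec, "sensitivity_spec"))
  if (!param_name %in% BIOPHYS_PARAM_NAMES) {
    stop(sprintf("unknown biophysical parameter `%s`", param_name), call. = FALSE)
  }
  withr::local_seed(param_seed(spec, param_name, 2L))
  nominal <- params[[param_name]]
  draws <- gaussian_draws(nominal, spec$n_samples, spec$rel_sd)
  fits <- lapply(draws, function(v) {
    tryCatch({
      repl <- stats::setNames(list(v), param_name)
      p2 <- do.call(update_params, c(list(params), repl))
      h <- impulse_response(p2, grid)
      fit_mlr_log(h$times, h$values)$params
    }, error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (sum(ok) < 2L) stop("all draws invalid", call. = FALSE)
  As <- vapply(fits[ok], `[[`, numeric(1), "A")
  mus <- vapply(fits[ok], `[[`, numeric(1), "mu")
  lams <- vapply(fits[ok], `[[`, numeric(1), "lam")
  structure(list(param_name = param_name, model = "biophysical->ldrw",
                 cv_A = cv_percent(As), cv_mu = cv_percent(mus),
                 cv_lam = cv_percent(lams),
                 n_effective = sum(ok), warn = mean(!ok) > 0.2,
                 A = As, mu = mus, lam = lams),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  if (!is.null(x$cv_output)) {
    cat(sprintf("<sensitivity_result> %s model, %s: CV = %.3f%% (n_eff = %d)\n",
                x$model, x$param_name, x$cv_output, x$n_effective))
  } else {
    cat(sprintf("<sensitivity_result> %s, %s: CV(A) = %.2f%%, CV(mu) = %.2f%%, CV(lambda) = %.2f%% (n_eff = %d)\n",
                x$model, x$param_name, x$cv_A, x$cv_mu, x$cv_lam, x$n_effective))
  }
  invisible(x)
}

#' Batch sensitivity table
#'
#' Runs [analysis_one()] over every parameter of the chosen model
#' (`analysis = 1`), or [analysis_two()] over the biophysical parameters
#' that pass the analysis-1 screening rule CV > 0.1 percent
#' (`analysis = 2`), and collects the CVs in a data frame (rows =
#' parameters).
#'
#' @param analysis 1 or 2.
#' @param model For analysis 1: `"ldrw"` or `"biophysical"`.
#' @inheritParams analysis_one
#' @export
sensitivity_table <- function(analysis = 1, model = c("ldrw", "biophysical"),
                              spec = sensitivity_spec(),
                              params = biophysical_params(),
                              grid = sim_grid(), theta = NULL) {
  model <- match.arg(model)
  if (analysis == 1) {
    nms <- if (model == "ldrw") LDRW_PARAM_NAMES else BIOPHYS_PARAM_NAMES
    if (model == "ldrw" && is.null(theta)) theta <- baseline_theta(params, grid)
    rows <- lapply(nms, function(nm) {
      r <- analysis_one(model, nm, spec, params, grid, theta)
      data.frame(param = nm, cv_output = r$cv_output, n_effective = r$n_effective)
    })
    do.call(rbind, rows)
  } else if (analysis == 2) {
    screen <- sensitivity_table(1, "biophysical", spec, params, grid)
    nms <- screen$param[screen$cv_output > 0.1]
    rows <- lapply(nms, function(nm) {
      r <- analysis_two(nm, spec, params, grid)
      data.frame(param = nm, cv_A = r$cv_A, cv_mu = r$cv_mu, cv_lam = r$cv_lam,
                 n_effective = r$n_effective)
    })
    do.call(rbind, rows)
  } else {
    stop("`analysis` must be 1 or 2", call. = FALSE)
  }
}
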