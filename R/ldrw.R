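#' Parameters of the LDRW indicator-dilution model
#'
#' The local density random walk (LDRW) model describes the concentration-time
#' curve of a solute detected downstream of a fast injection into a
#' convective-diffusive stream:
#' \deqn{C(t) = A e^{\lambda} \sqrt{\lambda / (2\pi\mu t)}
#'       \exp\{-(\lambda/2)(t/\mu + \mu/t)\}.}
#' `A` is the curve area; when the model is fitted to an impulse response it
#' is the dimensionless sweat-per-blood transfer gain (in the classical
#' indicator-dilution reading it is dose over volumetric flow, mol s m^-3).
#' `mu` (s) sets the transit-time scale, and `lam` is the dimensionless
#' skewness parameter, equal to half the Peclet number.
#'
#' @param A Curve area, > 0.
#' @param mu Transit-time scale in seconds, > 0.
#' @param lam Skewness parameter (Pe/2), > 0.
#' @return An object of class `ldrw_params`.
#' @export
ldrw_params <- function(A, mu, lam) {
  for (nm in c("A", "mu", "lam")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      stop(sprintf("invalid parameter: `%s` must be a single positive number", nm),
           call. = FALSE)
    }
  }
  structure(list(A = A, mu = mu, lam = lam), class = "ldrw_params")
}

#' @export
print.ldrw_params <- function(x, ...) {
  cat(sprintf("<ldrw_params> A = %.6g, mu = %.6g s, lambda = %.6g\n",
              x$A, x$mu, x$lam))
  invisible(x)
}

#' Evaluate the LDRW concentration-time curve
#'
#' Pointwise evaluation of the LDRW model. The essential singularity
#' `exp(-lambda*mu/(2t))` dominates as `t -> 0+`, so `t = 0` maps to 0 by
#' continuity; negative times are rejected.
#'
#' @param theta An `ldrw_params` object.
#' @param times Numeric vector of times in seconds, >= 0.
#' @return Numeric vector of non-negative concentrations.
#' @examples
#' ldrw_evaluate(ldrw_params(1, 1, 1), 1)  # 1/sqrt(2*pi)
#' @export
ldrw_evaluate <- function(theta, times) {
  stopifnot(inherits(theta, "ldrw_params"))
  if (any(times < 0)) stop("`times` must be non-negative", call. = FALSE)
  out <- numeric(length(times))
  pos <- times > 0
  t <- times[pos]
  out[pos] <- theta$A * exp(theta$lam) * sqrt(theta$lam / (2 * pi * theta$mu * t)) *
    exp(-(theta$lam / 2) * (t / theta$mu + theta$mu / t))
  out
}

#' Analytic moments of the LDRW curve
#'
#' @param theta An `ldrw_params` object.
#' @return A list with `area` (= A exactly), `mean_transit_time`
#'   (first moment, `mu * (1 + 1/lambda)`) and `peak_time`
#'   (`mu * (-1 + sqrt(1 + 4 lambda^2)) / (2 lambda)`). Note that the
#'   parameter `mu` itself equals the first moment only in the large-lambda
#'   (convection-dominated) limit; both readings of "mean transit time" are
#'   therefore available to the caller.
#' @export
ldrw_moments <- function(theta) {
  stopifnot(inherits(theta, "ldrw_params"))
  list(area = theta$A,
       mean_transit_time = theta$mu * (1 + 1 / theta$lam),
       peak_time = theta$mu * (-1 + sqrt(1 + 4 * theta$lam^2)) / (2 * theta$lam))
}

#' Fit LDRW parameters by log-domain multiple linear regression
#'
#' Exact linearisation of the LDRW model: with
#' `y = ln C + (1/2) ln t`, the model is linear in the basis `{1, t, 1/t}`
#' with slopes `beta1 = -lambda/(2 mu)` on `t` and `beta2 = -lambda mu / 2`
#' on `1/t`. Both slopes must be negative for an LDRW-shaped curve; the
#' parameters are recovered as `lambda = 2 sqrt(beta1 beta2)`,
#' `mu = sqrt(beta2 / beta1)` and
#' `A = exp(beta0 - lambda - (1/2) ln(lambda/(2 pi mu)))`.
#' Samples below 1\% of the curve maximum (or at non-positive times) are
#' excluded: the logarithm of near-zero tail values would otherwise dominate
#' the unweighted regression.
#'
#' @param times Numeric vector of sample times (s).
#' @param values Numeric vector of curve values (same length).
#' @return An object of class `ldrw_fit`: list with `params` (`ldrw_params`),
#'   `n_used`, `rss_log` (residual sum of squares in the log domain) and
#'   `converged`.
#' @examples
#' t <- seq(1, 400, by = 2)
#' fit_mlr_log(t, ldrw_evaluate(ldrw_params(0.02, 60, 3), t))
#' @export
fit_mlr_log <- function(times, values) {
  if (length(times) != length(values)) {
    stop("`times` and `values` must have the same length", call. = FALSE)
  }
  keep <- is.finite(times) & is.finite(values) & times > 0 &
    values >= 0.01 * max(values, na.rm = TRUE) & values > 0
  t <- times[keep]
  v <- values[keep]
  if (length(unique(t)) < 3L) {
    stop("need at least 3 strictly positive samples at distinct positive times",
         call. = FALSE)
  }
  y <- log(v) + 0.5 * log(t)
  fit <- stats::lm(y ~ t + I(1 / t))
  beta <- stats::coef(fit)
  b0 <- beta[[1]]; b1 <- beta[[2]]; b2 <- beta[[3]]
  if (!(b1 < 0 && b2 < 0)) {
    stop("fit failure: curve is not LDRW-shaped (non-negative log-domain slopes)",
         call. = FALSE)
  }
  lam <- 2 * sqrt(b1 * b2)
  mu <- sqrt(b2 / b1)
  A <- exp(b0 - lam - 0.5 * log(lam / (2 * pi * mu)))
  structure(list(params = ldrw_params(A, mu, lam),
                 n_used = length(t),
                 rss_log = sum(stats::resid(fit)^2),
                 converged = TRUE),
            class = "ldrw_fit")
}

#' @export
print.ldrw_fit <- function(x, ...) {
  cat(sprintf("<ldrw_fit> n_used = %d, rss_log = %.4g\n", x$n_used, x$rss_log))
  print(x$params)
  invisible(x)
}
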