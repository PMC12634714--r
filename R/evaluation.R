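#' Regression performance metrics
#'
#' Agreement metrics between an estimated and a reference series:
#' RMSE = sqrt(mean((est - ref)^2)), MAE = mean(|est - ref|),
#' RMSPE = 100 * sqrt(mean(((est - ref)/ref)^2)), the Pearson correlation
#' coefficient and the coefficient of determination
#' R^2 = 1 - SS_res/SS_tot (residuals against `ref`).
#'
#' @param est Numeric vector of estimates (mol m^-3).
#' @param ref Numeric vector of reference values, same length (>= 2).
#' @return A list of class `metrics_bundle` with fields `rmse`, `mae`,
#'   `rmspe` (percent), `pearson_r`, `r_squared` and `n`. When `ref` is
#'   constant the correlation fields are `NA` (undefined). When `ref`
#'   contains zeros, `rmspe` is an error.
#' @examples
#' regression_metrics(c(1, 2, 3), c(1, 2, 4))
#' @export
regression_metrics <- function(est, ref) {
  if (length(est) != length(ref)) stop("`est` and `ref` must have the same length", call. = FALSE)
  if (length(ref) < 2L) stop("need at least 2 points", call. = FALSE)
  err <- est - ref
  rmspe <- if (any(ref == 0)) {
    stop("RMSPE undefined: `ref` contains zeros", call. = FALSE)
  } else {
    100 * sqrt(mean((err / ref)^2))
  }
  if (stats::var(ref) > 0) {
    pearson_r <- if (stats::var(est) > 0) stats::cor(est, ref) else NA_real_
    r_squared <- 1 - sum(err^2) / sum((ref - mean(ref))^2)
  } else {
    pearson_r <- NA_real_
    r_squared <- NA_real_
  }
  structure(list(rmse = sqrt(mean(err^2)), mae = mean(abs(err)), rmspe = rmspe,
                 pearson_r = pearson_r, r_squared = r_squared,
                 n = length(ref)),
            class = "metrics_bundle")
}

#' @export
print.metrics_bundle <- function(x, ...) {
  cat(sprintf(paste0("<metrics_bundle> n = %d\n",
                     "  RMSE  = %.4g mmol/L   MAE = %.4g mmol/L   RMSPE = %.4g%%\n",
                     "  R     = %.4g          R^2 = %.4g\n"),
              x$n, x$rmse, x$mae, x$rmspe, x$pearson_r, x$r_squared))
  invisible(x)
}

#' Root mean square difference between two estimate series
#'
#' Same formula as the RMSE, applied to two estimate vectors to quantify
#' model-to-model agreement.
#'
#' @param x,y Numeric vectors of equal length.
#' @export
rmsd <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have the same length", call. = FALSE)
  sqrt(mean((x - y)^2))
}

#' Akaike information criterion (Gaussian residuals) and its small-sample
#' correction
#'
#' Uses the i.i.d. Gaussian-residual convention with profiled variance,
#' `AIC = n log(rss/n) + 2k` (additive constants dropped: only AIC
#' differences between models fitted to the same data are meaningful), and
#' `AICc = AIC + 2k(k+1)/(n-k-1)`.
#'
#' @param rss Residual sum of squares, > 0.
#' @param n Sample count; must exceed `k + 1`.
#' @param k Number of estimated parameters.
#' @return For [aicc()], a list with `aic`, `aicc` and `correction`.
#' @examples
#' aicc(rss = 10, n = 108, k = 3)
#' @export
aicc <- function(rss, n, k) {
  if (rss <= 0) stop("`rss` must be positive", call. = FALSE)
  if (n <= k + 1) stop("`n` must exceed `k + 1` for the small-sample correction", call. = FALSE)
  aic <- n * log(rss / n) + 2 * k
  corr <- 2 * k * (k + 1) / (n - k - 1)
  list(aic = aic, aicc = aic + corr, correction = corr)
}
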