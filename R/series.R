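#' Timestamped glucose concentration trace
#'
#' Container for a glucose concentration time series. All concentrations are
#' stored in mol m^-3, which is numerically identical to mmol L^-1 (and equal
#' to 1000 umol L^-1). Times are in seconds and must be strictly increasing.
#'
#' @param times Numeric vector of times in seconds, strictly increasing.
#' @param values Numeric vector of non-negative concentrations in mol m^-3.
#' @param label Role tag, one of `"blood"`, `"sweat"`, `"estimated"`.
#' @return An object of class `concentration_series`: a data frame with
#'   columns `times` and `values` and a `label` attribute.
#' @examples
#' blood <- concentration_series(c(0, 300, 600), c(5.5, 6.1, 5.8), "blood")
#' @export
concentration_series <- function(times, values, label = c("blood", "sweat", "estimated")) {
  label <- match.arg(label)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("`times` and `values` must have the same length", call. = FALSE)
  }
  if (length(times) < 1L) stop("at least one sample is required", call. = FALSE)
  if (anyNA(times) || anyNA(values)) stop("missing values are not allowed", call. = FALSE)
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (any(values < 0)) stop("concentrations must be non-negative", call. = FALSE)
  out <- data.frame(times = times, values = values)
  attr(out, "label") <- label
  class(out) <- c("concentration_series", "data.frame")
  out
}

#' @export
print.concentration_series <- function(x, ...) {
  cat(sprintf("<concentration_series> label = %s, n = %d, t in [%g, %g] s\n",
              attr(x, "label"), nrow(x), min(x$times), max(x$times)))
  cat(sprintf("  concentration [mol m^-3]: min %.4g, mean %.4g, max %.4g\n",
              min(x$values), mean(x$values), max(x$values)))
  invisible(x)
}

# linear interpolation of a series onto an arbitrary grid; values are held
# constant beyond the observed range (steady pre/post history)
interp_series <- function(series, at) {
  if (nrow(series) == 1L) return(rep(series$values, length(at)))
  stats::approx(series$times, series$values, xout = at, rule = 2)$y
}

# trapezoidal area under a sampled curve
trapz_area <- function(times, values) {
  if (length(times) < 2L) return(0)
  pracma::trapz(times, values)
}
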