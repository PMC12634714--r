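#' Read a concentration time series from CSV
#'
#' Expects a two-column CSV with header `time_s,concentration_mmol_per_L`
#' (blood scale) or `time_s,concentration_umol_per_L` (sweat scale); comment
#' lines starting with `#` are ignored. Values are converted to mol m^-3
#' (1 mmol L^-1 = 1 mol m^-3; 1 umol L^-1 = 1e-3 mol m^-3).
#'
#' @param path Path to the CSV file.
#' @param unit `"mmol_per_L"` or `"umol_per_L"`; determines the expected
#'   concentration column name and the conversion.
#' @param label Role tag for the series; defaults to `"blood"` for
#'   mmol-scale files and `"sweat"` for umol-scale files.
#' @param time_unit `"s"` (default) or `"min"`; minute-stamped files are
#'   converted to seconds (the expected time column is then `time_min`).
#' @return A `concentration_series` in mol m^-3.
#' @export
read_series <- function(path, unit = c("mmol_per_L", "umol_per_L"),
                        label = NULL, time_unit = c("s", "min")) {
  unit <- match.arg(unit)
  time_unit <- match.arg(time_unit)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  time_col <- paste0("time_", time_unit)
  conc_col <- paste0("concentration_", unit)
  for (col in c(time_col, conc_col)) {
    if (!col %in% names(df)) {
      stop(sprintf("format error in `%s`: missing column `%s` (found: %s)",
                   path, col, paste(names(df), collapse = ", ")), call. = FALSE)
    }
  }
  times <- df[[time_col]] * if (time_unit == "min") 60 else 1
  values <- df[[conc_col]] * if (unit == "umol_per_L") 1e-3 else 1
  if (anyDuplicated(times)) stop("validation error: duplicate timestamps", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("validation error: times must be strictly increasing", call. = FALSE)
  }
  if (any(values < 0)) stop("validation error: negative concentration", call. = FALSE)
  if (is.null(label)) label <- if (unit == "mmol_per_L") "blood" else "sweat"
  concentration_series(times, values, label)
}

#' Write a concentration time series to CSV
#'
#' Inverse of [read_series()]. A comment header records the package version,
#' the seed (if supplied) and MD5 checksums of any input files, so outputs
#' are traceable and reruns are verifiable.
#'
#' @param series A `concentration_series` (values in mol m^-3).
#' @param path Output path.
#' @param unit Output concentration unit (`"mmol_per_L"` or `"umol_per_L"`).
#' @param seed Optional integer recorded in the header.
#' @param inputs Optional character vector of input file paths to checksum.
#' @export
write_series <- function(series, path, unit = c("mmol_per_L", "umol_per_L"),
                         seed = NULL, inputs = NULL) {
  stopifnot(inherits(series, "concentration_series"))
  unit <- match.arg(unit)
  values <- series$values / if (unit == "umol_per_L") 1e-3 else 1
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(run_header(seed, inputs), con)
  utils::write.csv(stats::setNames(data.frame(series$times, values),
                                   c("time_s", paste0("concentration_", unit))),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

run_header <- function(seed = NULL, inputs = NULL) {
  hdr <- sprintf("# sweat2blood %s",
                 as.character(utils::packageVersion("sweat2blood")))
  if (!is.null(seed)) hdr <- c(hdr, sprintf("# seed: %d", as.integer(seed)))
  if (!is.null(inputs)) {
    sums <- tools::md5sum(inputs)
    hdr <- c(hdr, sprintf("# input %s md5 %s", names(sums), unname(sums)))
  }
  hdr
}

#' Read biophysical parameters from a YAML file
#'
#' The file holds a flat mapping using the parameter names of
#' [biophysical_params()]; absent keys fall back to the defaults, unknown
#' keys are an error.
#'
#' @param path Path to the YAML file (`NULL` returns the defaults).
#' @return A `biophysical_params` object.
#' @export
read_params <- function(path = NULL) {
  if (is.null(path)) return(biophysical_params())
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) return(biophysical_params())
  do.call(biophysical_params, vals)
}

#' Write biophysical parameters to YAML
#' @param params A `biophysical_params` object.
#' @param path Output path.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "biophysical_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' Read/write LDRW parameters (YAML)
#'
#' Flat YAML mapping with keys `A`, `mu`, `lam`.
#'
#' @param path File path.
#' @return [read_theta()] returns an `ldrw_params` object.
#' @export
read_theta <- function(path) {
  vals <- yaml::read_yaml(path)
  ldrw_params(vals$A, vals$mu, vals$lam)
}

#' @rdname read_theta
#' @param theta An `ldrw_params` object.
#' @export
write_theta <- function(theta, path) {
  stopifnot(inherits(theta, "ldrw_params"))
  yaml::write_yaml(unclass(theta), path)
  invisible(path)
}
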