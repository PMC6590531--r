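#' Yearly surveillance table of the five model rates
#'
#' Validating constructor for a table of observed yearly rates: complication
#' rate lambda, combined removal rate theta, incidence, severe-disability-
#' plus-complication-mortality rate nu + delta, and mortality mu.  The
#' packaged example (`surveillance_example()`) holds the Fujian Province
#' 2012--2016 series that the canonical coefficient defaults were fitted
#' from.
#'
#' @param year integer calendar years, strictly increasing.
#' @param lambda,theta,incidence,nu_delta,mu numeric rate series, all
#'   finite and >= 0, same length as `year`.
#' @return A `data.frame` of class `surveillance_table`.
#' @export
surveillance_table <- function(year, lambda, theta, incidence, nu_delta, mu) {
  tab <- data.frame(year = as.integer(year), lambda = as.numeric(lambda),
                    theta = as.numeric(theta),
                    incidence = as.numeric(incidence),
                    nu_delta = as.numeric(nu_delta), mu = as.numeric(mu))
  if (nrow(tab) < 1L) stop("surveillance table must have at least one row")
  if (anyNA(tab)) {
    bad <- which(rowSums(is.na(tab)) > 0)[1L]
    stop("missing or non-numeric cell in surveillance table row ", bad)
  }
  if (anyDuplicated(tab$year)) {
    bad <- tab$year[anyDuplicated(tab$year)]
    stop("duplicate year in surveillance table: ", bad)
  }
  if (is.unsorted(tab$year, strictly = TRUE))
    stop("surveillance table years must be strictly increasing")
  rates <- as.matrix(tab[, -1L])
  if (!all(is.finite(rates)))
    stop("surveillance rates must all be finite")
  if (any(rates < 0)) {
    bad <- which(rowSums(rates < 0) > 0)[1L]
    stop("negative rate in surveillance table row ", bad)
  }
  class(tab) <- c("surveillance_table", "data.frame")
  tab
}

table_columns <- c("year", "lambda", "theta", "incidence", "nu_delta", "mu")

#' Read a surveillance table from CSV
#'
#' Expects the columns `year,lambda,theta,incidence,nu_delta,mu`.  Rejects
#' missing cells, non-numeric entries, duplicate years and negative rates,
#' naming the offending row.
#'
#' @param file path of (or connection to) the CSV file.
#' @return A [surveillance_table()].
#' @export
#' @examples
#' tab <- read_surveillance_table(surveillance_example())
#' tab$lambda[1]  # 0.0211
read_surveillance_table <- function(file) {
  raw <- utils::read.csv(file, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  missing_cols <- setdiff(table_columns, names(raw))
  if (length(missing_cols))
    stop("surveillance CSV lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0L) stop("surveillance CSV has an empty body")
  num <- suppressWarnings(lapply(raw[table_columns], as.numeric))
  for (nm in table_columns) {
    bad <- which(is.na(num[[nm]]))
    if (length(bad))
      stop("non-numeric '", nm, "' in surveillance CSV row ", bad[1L])
  }
  do.call(surveillance_table, num)
}

#' Path of the packaged Fujian Province 2012--2016 surveillance CSV
#' @return A file path.
#' @export
surveillance_example <- function() {
  system.file("extdata", "fujian_rates_2012_2016.csv", package = "diabsde",
              mustWork = TRUE)
}

#' Through-origin least-squares slope
#'
#' Fits y = s * t without an intercept (the rate laws have no constant
#' term), minimising the residual sum of squares; the closed form is
#' s = sum(t y) / sum(t^2).
#'
#' @param values numeric rate series.
#' @param t numeric time-index series of the same length, not all zero.
#' @return The fitted slope (length-1 numeric).
#' @export
fit_slope <- function(values, t) {
  if (length(values) != length(t) || length(t) < 1L)
    stop("values and t must have equal length >= 1")
  if (!all(is.finite(values)) || !all(is.finite(t)))
    stop("values and t must be finite")
  st2 <- sum(t^2)
  if (st2 == 0) stop("undefined fit: all time indices are zero")
  sum(t * values) / st2
}

#' Calibrate the linear rate coefficients from a surveillance table
#'
#' Converts calendar years to the model time index t = year - baseline_year
#' and fits each of the five rate series through the origin.  The baseline
#' defaults to 2011 so that the packaged 2012--2016 table maps to
#' t = 1..5, which reproduces the canonical lambda and incidence slopes to
#' two decimals.  Note the printed canonical nu+delta (0.007) and mu
#' (0.002) slopes are *not* recovered by this fit (or any simple variant);
#' the package keeps the canonical values as simulation defaults and
#' reports fitted values separately.
#'
#' @param table a [surveillance_table()].
#' @param baseline_year integer year mapped to t = 0; must precede the
#'   first table year.
#' @return An object of class `calibration_result`: `slopes` (a
#'   [linear_coefficients()]), `rss` (per-series residual sum of squares)
#'   and `t_index` (year -> t mapping).
#' @export
#' @examples
#' calibrate(read_surveillance_table(surveillance_example()))
calibrate <- function(table, baseline_year = 2011L) {
  stopifnot(inherits(table, "surveillance_table"))
  if (baseline_year >= table$year[1L])
    stop("baseline_year must precede the first table year")
  t <- table$year - baseline_year
  series <- table_columns[-1L]
  slopes <- vapply(series, function(nm) fit_slope(table[[nm]], t), 0)
  rss <- vapply(series, function(nm) sum((table[[nm]] - slopes[[nm]] * t)^2), 0)
  structure(list(
    slopes = linear_coefficients(lam_slope = slopes[["lambda"]],
                                 theta_slope = slopes[["theta"]],
                                 inc_slope = slopes[["incidence"]],
                                 nu_delta_slope = slopes[["nu_delta"]],
                                 mu_slope = slopes[["mu"]]),
    rss = rss,
    t_index = stats::setNames(t, table$year),
    baseline_year = baseline_year),
    class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  s <- x$slopes
  cat("Through-origin calibration (t = year -", x$baseline_year, ")\n")
  cat(sprintf("  lambda ~ %.5f t   theta ~ %.5f t   I ~ %.5f t\n",
              s$lam_slope, s$theta_slope, s$inc_slope))
  cat(sprintf("  nu+delta ~ %.5f t   mu ~ %.5f t\n",
              s$nu_delta_slope, s$mu_slope))
  invisible(x)
}

#' Export a calibration result as JSON
#'
#' @param result a `calibration_result`.
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_calibration_json <- function(result, file) {
  stopifnot(inherits(result, "calibration_result"))
  out <- list(slopes = unclass(result$slopes),
              rss = as.list(result$rss),
              t_index = as.list(result$t_index),
              baseline_year = result$baseline_year)
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' Generate a synthetic surveillance table with known slopes
#'
#' Each rate in row i is `slope * t_i + rnorm(1, 0, noise_sd)`, truncated
#' at zero; t_i = 1..n_years, with calendar years starting the year after
#' the baseline.  Deterministic given `seed`.  Used for parameter-recovery
#' studies where the ground truth is known exactly.
#'
#' @param slopes a [linear_coefficients()] object (the ground truth).
#' @param n_years number of yearly rows (>= 1).
#' @param noise_sd standard deviation of the additive Gaussian rate noise
#'   (>= 0).
#' @param seed integer seed; `NULL` draws from the current RNG stream.
#' @param baseline_year calendar year mapped to t = 0.
#' @return A [surveillance_table()].
#' @export
generate_fixture <- function(slopes = linear_coefficients(), n_years = 5L,
                             noise_sd = 0, seed = NULL,
                             baseline_year = 2011L) {
  if (n_years < 1L) stop("n_years must be >= 1")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("noise_sd must be a number >= 0")
  if (!is.null(seed)) set.seed(seed)
  t <- seq_len(n_years)
  s <- c(slopes$lam_slope, slopes$theta_slope, slopes$inc_slope,
         slopes$nu_delta_slope, slopes$mu_slope)
  rates <- outer(t, s) + matrix(stats::rnorm(n_years * 5L, 0, noise_sd),
                                n_years, 5L)
  rates <- pmax(rates, 0)
  surveillance_table(year = baseline_year + t, lambda = rates[, 1L],
                     theta = rates[, 2L], incidence = rates[, 3L],
                     nu_delta = rates[, 4L], mu = rates[, 5L])
}

#' Write a surveillance table as CSV
#'
#' Inverse of [read_surveillance_table()]; the packaged example file was
#' produced by this writer, so regeneration is byte-identical.
#'
#' @param table a [surveillance_table()].
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_surveillance_csv <- function(table, file) {
  stopifnot(inherits(table, "surveillance_table"))
  utils::write.csv(as.data.frame(table)[table_columns], file,
                   row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(file)
}

# Fujian Province 2012-2016 yearly rates (calibration source data).
fujian_table <- function() {
  surveillance_table(
    year = 2012:2016,
    lambda = c(0.0211, 0.0401, 0.0612, 0.0812, 0.0991),
    theta = c(0.0089, 0.0101, 0.0293, 0.0387, 0.0591),
    incidence = c(0.0573, 0.1010, 0.1536, 0.2006, 0.2436),
    nu_delta = c(0.00526, 0.00611, 0.00650, 0.00706, 0.00664),
    mu = c(0.00191, 0.00081, 0.00118, 0.00157, 0.00198))
}
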