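#' Read a daily temperature series
#'
#' @param path CSV with columns `date` (ISO-8601) and `mean_temp_C`.
#' @return data.frame with `date` (Date) and `mean_temp_C`; duplicate dates
#'   are an error.
#' @export
read_temperature_csv <- function(path) {
  if (!file.exists(path)) stop("temperature file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "mean_temp_C") %in% names(raw)))
    stop("temperature file needs columns 'date' and 'mean_temp_C'")
  d <- as.Date(raw$date)
  if (anyNA(d)) stop("unparseable date(s) in temperature file")
  if (anyDuplicated(d)) stop("duplicate date(s) in temperature file")
  data.frame(date = d, mean_temp_C = as.numeric(raw$mean_temp_C))
}

#' Yearly mean temperatures for a season window
#'
#' Aggregates a daily series to one mean per calendar year, either over the
#' whole year or over the breeding season (May-July). Years missing more
#' than a stated fraction of the window's days are flagged and excluded.
#'
#' @param series data.frame `date`, `mean_temp_C` (see
#'   [read_temperature_csv]).
#' @param window `"annual"` or `"breeding_season"` (months 5-7).
#' @param max_missing_frac exclude years missing more than this fraction of
#'   the window's days (default 0.2).
#' @return data.frame `year`, `mean_temp_C`, `n_days`; excluded years are
#'   attached as attribute `"excluded_years"`.
#' @export
seasonal_aggregate <- function(series, window = c("annual", "breeding_season"),
                               max_missing_frac = 0.2) {
  window <- match.arg(window)
  stopifnot(all(c("date", "mean_temp_C") %in% names(series)))
  keep <- !is.na(series$mean_temp_C)
  if (window == "breeding_season")
    keep <- keep & as.integer(format(series$date, "%m")) %in% 5:7
  s <- series[keep, , drop = FALSE]
  if (!nrow(s)) stop("no observations in the requested window")
  yr <- as.integer(format(s$date, "%Y"))
  agg <- data.frame(year = sort(unique(yr)))
  agg$mean_temp_C <- as.numeric(tapply(s$mean_temp_C, yr, mean))
  agg$n_days <- as.integer(tapply(s$mean_temp_C, yr, length))
  full <- if (window == "annual") 365 else 92
  bad <- agg$n_days < (1 - max_missing_frac) * full
  excluded <- agg$year[bad]
  if (length(excluded))
    message("excluding year(s) with excessive missingness: ",
            paste(excluded, collapse = ", "))
  agg <- agg[!bad, , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "excluded_years") <- excluded
  agg
}

#' Linear warming trend
#'
#' Ordinary least squares of yearly mean temperature on year, the standard
#' way to state a warming rate in degrees C per year with its standard
#' error, t statistic and two-sided p value.
#'
#' @param yearly data.frame `year`, `mean_temp_C` (see
#'   [seasonal_aggregate]).
#' @return An object of class `warming_estimate`: `slope_C_per_yr`, `se`,
#'   `t`, `p_value`, `n_years`, and the underlying `lm` fit.
#' @export
fit_trend <- function(yearly) {
  stopifnot(all(c("year", "mean_temp_C") %in% names(yearly)))
  if (nrow(yearly) < 3) stop("need at least 3 years to fit a trend")
  fit <- stats::lm(mean_temp_C ~ year, data = yearly)
  co <- summary(fit)$coefficients
  structure(list(slope_C_per_yr = co["year", "Estimate"],
                 se = co["year", "Std. Error"],
                 t = co["year", "t value"],
                 p_value = co["year", "Pr(>|t|)"],
                 n_years = nrow(yearly), fit = fit),
            class = "warming_estimate")
}

#' @export
print.warming_estimate <- function(x, ...) {
  cat(sprintf("Warming trend: %.4g +/- %.2g C/yr (t = %.3g, p = %.3g, n = %d years)\n",
              x$slope_C_per_yr, x$se, x$t, x$p_value, x$n_years))
  invisible(x)
}

#' Expected isotherm displacement
#'
#' Converts a warming rate into the expected upslope displacement of
#' temperature isotherms: warming over the survey interval divided by the
#' lapse rate (the rate at which temperature decreases with elevation,
#' ~0.6 degrees C per 100 m in mountains). This is the climate-side
#' yardstick against which abundance and range shifts are compared.
#'
#' @param slope_C_per_yr warming rate; either a number or a
#'   `warming_estimate`.
#' @param span_years interval between the survey periods. The default 30.25
#'   years is the package's resolution of the "three decades" between a
#'   1990-1993 historical campaign and a 2023 resurvey (see the methods
#'   vignette for why the interval is ambiguous at the +/- 1 yr level).
#' @param lapse_C_per_m lapse rate (default 0.006 C/m = 0.6 C / 100 m);
#'   must be positive.
#' @return List: `shift_m` (displacement in meters) and `warming_C` (the
#'   intermediate temperature change over the interval).
#' @examples
#' isotherm_shift(0.06, span_years = 30, lapse_C_per_m = 0.006)$shift_m # 300
#' @export
isotherm_shift <- function(slope_C_per_yr, span_years = 30.25,
                           lapse_C_per_m = 0.006) {
  if (inherits(slope_C_per_yr, "warming_estimate"))
    slope_C_per_yr <- slope_C_per_yr$slope_C_per_yr
  stopifnot(is.numeric(slope_C_per_yr), length(slope_C_per_yr) == 1L)
  if (span_years <= 0) stop("span_years must be positive")
  if (lapse_C_per_m <= 0) stop("lapse rate must be positive")
  warming <- slope_C_per_yr * span_years
  list(shift_m = warming / lapse_C_per_m, warming_C = warming)
}
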