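#' HOF curve parameters
#'
#' Bundles the five parameters of the Huisman-Olff-Fresco (HOF) response
#' curve used as the abundance surface: the abundance scale `M` and the four
#' shape parameters `a, b, c, d` of the two logistic terms. Expected
#' abundance at standardized elevation `x` is
#' \deqn{\lambda(x) = M \cdot \frac{1}{1+e^{a+bx}} \cdot \frac{1}{1+e^{c-dx}}.}
#' The product of the two logistic terms can describe flat, monotone and
#' unimodal responses along the gradient.
#'
#' @param M non-negative abundance scale (expected count per replicate when
#'   both logistic terms saturate at 1).
#' @param a,b,c,d real shape parameters.
#' @return An object of class `hof_params`.
#' @examples
#' hof_lambda(hof_params(4, 0, 0, 0, 0), x = 0.3) # both terms 1/2 -> M/4
#' @export
hof_params <- function(M, a, b, c, d) {
  stopifnot(is.numeric(M), length(M) == 1L, is.finite(M), M >= 0)
  for (v in list(a, b, c, d)) stopifnot(is.numeric(v), length(v) == 1L, is.finite(v))
  structure(list(M = M, a = a, b = b, c = c, d = d), class = "hof_params")
}

#' @export
print.hof_params <- function(x, ...) {
  cat(sprintf("HOF curve: M = %.4g, a = %.4g, b = %.4g, c = %.4g, d = %.4g\n",
              x$M, x$a, x$b, x$c, x$d))
  invisible(x)
}

#' Evaluate a HOF response curve
#'
#' Computes expected abundance \eqn{\lambda(x)} on the standardized elevation
#' scale. The logistic terms are evaluated through `plogis`, i.e. in a
#' numerically safe form that cannot overflow for large `|a + bx|`, so the
#' function is total: every finite input yields a finite value in `[0, M]`.
#'
#' @param params a [hof_params] object, or a list with elements M, a, b, c, d
#'   (each possibly vectorized over posterior draws).
#' @param x standardized elevation (numeric vector).
#' @return Expected abundance, recycled over `x` and the parameter vectors.
#' @export
hof_lambda <- function(params, x) {
  params$M * stats::plogis(-(params$a + params$b * x)) *
    stats::plogis(-(params$c - params$d * x))
}

#' Elevation standardizer
#'
#' Centers elevations at the mean of the station elevations and scales by two
#' standard deviations (the standardization convention commonly recommended
#' for regression inputs). The same standardizer used for fitting must be
#' reused for prediction grids.
#'
#' @param elevations_m station elevations in meters used to define the
#'   transform, or `NULL` when `center_m`/`scale_m` are given directly.
#' @param center_m,scale_m explicit transform constants (meters); `scale_m`
#'   must be positive.
#' @return An object of class `elev_standardizer` with fields `center_m`,
#'   `scale_m`.
#' @examples
#' s <- elev_standardizer(center_m = 800, scale_m = 600)
#' standardize(1400, s) # 1.0
#' @export
elev_standardizer <- function(elevations_m = NULL, center_m = NULL, scale_m = NULL) {
  if (!is.null(elevations_m)) {
    stopifnot(is.numeric(elevations_m), length(elevations_m) >= 2L)
    center_m <- mean(elevations_m)
    scale_m <- 2 * stats::sd(elevations_m)
  }
  if (is.null(center_m) || is.null(scale_m))
    stop("provide either elevations_m or both center_m and scale_m")
  if (!is.finite(scale_m) || scale_m <= 0)
    stop("scale_m must be positive (constant elevations cannot be standardized)")
  structure(list(center_m = center_m, scale_m = scale_m),
            class = "elev_standardizer")
}

#' @rdname elev_standardizer
#' @param elev_m elevations in meters.
#' @param s an `elev_standardizer`.
#' @export
standardize <- function(elev_m, s) {
  stopifnot(inherits(s, "elev_standardizer"))
  (elev_m - s$center_m) / s$scale_m
}

#' @rdname elev_standardizer
#' @param x standardized elevations.
#' @export
unstandardize <- function(x, s) {
  stopifnot(inherits(s, "elev_standardizer"))
  x * s$scale_m + s$center_m
}

#' Prediction grid over the sampled gradient
#'
#' @param from,to gradient bounds in meters; defaults cover the lowest and
#'   highest station elevations of the emulated study design (201-1443 m).
#' @param by grid step in meters.
#' @return Numeric vector of elevations.
#' @export
elevation_grid <- function(from = 201, to = 1443, by = 1) {
  stopifnot(from < to, by > 0)
  seq(from, to, by = by)
}

#' Elevation of maximum expected abundance
#'
#' Grid search for the optimum elevation: the grid point where the HOF curve
#' attains its maximum. Ties are broken toward the lowest elevation. A curve
#' with `M = 0` has no optimum and returns `NA` with a warning.
#'
#' @param params a [hof_params] object.
#' @param grid elevation grid in meters.
#' @param s the `elev_standardizer` used when the curve was fitted.
#' @return Optimum elevation in meters (length 1), or `NA_real_`.
#' @export
find_optimum <- function(params, grid, s) {
  stopifnot(length(grid) >= 1L)
  if (params$M == 0) {
    warning("curve has M = 0: optimum elevation undefined")
    return(NA_real_)
  }
  lam <- hof_lambda(params, standardize(grid, s))
  grid[which.max(lam)] # which.max returns the first (lowest-elevation) tie
}

#' Range-limit rule
#'
#' A species is considered present at an elevation when its median expected
#' abundance exceeds an absolute threshold *or* a stated fraction of the
#' curve's maximum. The defaults (0.2 absolute, 15% of maximum) follow the
#' stricter of the two threshold pairs in use for this analysis style; the
#' laxer variant (0.1 absolute) can be requested explicitly.
#'
#' @param abs_threshold absolute abundance threshold (default 0.2).
#' @param rel_fraction fraction of the maximum abundance (default 0.15).
#' @return An object of class `range_rule`.
#' @export
range_rule <- function(abs_threshold = 0.2, rel_fraction = 0.15) {
  stopifnot(abs_threshold >= 0, rel_fraction >= 0, rel_fraction <= 1)
  structure(list(abs_threshold = abs_threshold, rel_fraction = rel_fraction),
            class = "range_rule")
}

#' Elevational range limits of an abundance profile
#'
#' Scans a (median) abundance profile along the grid and returns the lowest
#' and highest elevations where the [range_rule] holds. When the rule holds
#' nowhere the species has no modeled range and both limits are `NA`.
#'
#' @param lambda expected abundance aligned to `grid`.
#' @param grid elevation grid in meters.
#' @param rule a [range_rule].
#' @return Named numeric vector `c(low_m, high_m)`.
#' @export
range_limits <- function(lambda, grid, rule = range_rule()) {
  stopifnot(length(lambda) == length(grid))
  inr <- range_indicator(lambda, rule)
  if (!any(inr)) return(c(low_m = NA_real_, high_m = NA_real_))
  c(low_m = min(grid[inr]), high_m = max(grid[inr]))
}

# elementwise presence under the rule (shared by range_limits and the
# per-elevation change classifier)
range_indicator <- function(lambda, rule) {
  lambda > rule$abs_threshold | lambda > rule$rel_fraction * max(lambda)
}
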