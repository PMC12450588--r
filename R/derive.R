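#' Highest density interval
#'
#' Narrowest interval containing a stated posterior mass, computed with
#' `coda::HPDinterval`. 89% intervals are the package-wide convention for
#' all posterior summaries.
#'
#' @param x numeric draws.
#' @param prob interval mass (default 0.89).
#' @return `c(lower, upper)`.
#' @export
hdi <- function(x, prob = 0.89) {
  x <- x[is.finite(x)]
  if (!length(x)) return(c(NA_real_, NA_real_))
  if (stats::var(x) == 0) return(c(x[1], x[1]))
  h <- coda::HPDinterval(coda::as.mcmc(x), prob = prob)
  c(h[1, "lower"], h[1, "upper"])
}

#' Expected-abundance profile from posterior draws
#'
#' Evaluates the HOF curve of every retained draw on the elevation grid and
#' summarizes each elevation by the posterior median and 89% HDI.
#'
#' @param fit an `nmix_fit` (see [fit_species]).
#' @param period `"historical"` or `"modern"`.
#' @param grid elevation grid in meters.
#' @return An object of class `abundance_profile`: `species_code`, `period`,
#'   `grid_m`, `lambda` (draw x elevation matrix), `median`, `hdi`
#'   (elevation x 2 matrix).
#' @export
profile_from_draws <- function(fit, period = c("historical", "modern"),
                               grid = elevation_grid()) {
  stopifnot(inherits(fit, "nmix_fit"))
  period <- match.arg(period)
  sfx <- if (period == "historical") "hist" else "mod"
  d <- fit$draws
  lam <- hof_lambda_draws(d[[paste0("M_", sfx)]], d[[paste0("a_", sfx)]],
                          d[[paste0("b_", sfx)]], d[[paste0("c_", sfx)]],
                          d[[paste0("d_", sfx)]],
                          standardize(grid, fit$standardizer))
  profile_from_lambda(lam, grid, fit$species_code, period)
}

# draws x grid HOF evaluation (vectorized over both)
hof_lambda_draws <- function(M, a, b, c, d, xg) {
  t1 <- stats::plogis(-(outer(b, xg) + a))
  t2 <- stats::plogis(-(sweep(-outer(d, xg), 1, c, "+")))
  M * t1 * t2
}

# build an abundance_profile from an existing lambda matrix
profile_from_lambda <- function(lam, grid, species_code = NA_character_,
                                period = NA_character_) {
  med <- apply(lam, 2, stats::median)
  hd <- t(apply(lam, 2, hdi))
  colnames(hd) <- c("lower", "upper")
  structure(list(species_code = species_code, period = period,
                 grid_m = grid, lambda = lam, median = med, hdi = hd),
            class = "abundance_profile")
}

#' Per-elevation abundance-change classes
#'
#' Compares the historical and modern 89% HDIs of expected abundance at each
#' grid elevation. Inside both periods' ranges: overlapping HDIs mean
#' `stable`; a modern HDI entirely above the historical one means
#' `increase`, entirely below means `decrease`. Elevations inside only the
#' modern range are `range_expansion`; inside only the historical range,
#' `range_contraction`; inside neither, `outside`. Ranges are the
#' [range_limits] of each period's median profile.
#'
#' @param hist,mod `abundance_profile`s on the same grid.
#' @param rule a [range_rule] defining the ranges.
#' @return Factor over the grid with levels stable, increase, decrease,
#'   range_expansion, range_contraction, outside; the two periods' limits
#'   are attached as attributes `limits_hist` and `limits_mod`.
#' @export
classify_elevation_change <- function(hist, mod, rule = range_rule()) {
  stopifnot(inherits(hist, "abundance_profile"), inherits(mod, "abundance_profile"))
  if (!isTRUE(all.equal(hist$grid_m, mod$grid_m)))
    stop("profiles are on different grids")
  in_h <- range_indicator(hist$median, rule)
  in_m <- range_indicator(mod$median, rule)
  cls <- rep("outside", length(hist$grid_m))
  cls[in_h & !in_m] <- "range_contraction"
  cls[!in_h & in_m] <- "range_expansion"
  both <- in_h & in_m
  overlap <- !(mod$hdi[, "lower"] > hist$hdi[, "upper"] |
                 mod$hdi[, "upper"] < hist$hdi[, "lower"])
  cls[both & overlap] <- "stable"
  cls[both & !overlap & mod$hdi[, "lower"] > hist$hdi[, "upper"]] <- "increase"
  cls[both & !overlap & mod$hdi[, "upper"] < hist$hdi[, "lower"]] <- "decrease"
  out <- factor(cls, levels = c("stable", "increase", "decrease",
                                "range_expansion", "range_contraction", "outside"))
  attr(out, "limits_hist") <- range_limits(hist$median, hist$grid_m, rule)
  attr(out, "limits_mod") <- range_limits(mod$median, mod$grid_m, rule)
  out
}

#' Optimum elevations, their HDIs, and the between-period shift
#'
#' The per-draw optimum is the grid elevation maximizing that draw's HOF
#' curve; the 89% HDI is taken over these per-draw optima. The point
#' estimate is, by default, the optimum of the per-elevation posterior
#' median curve (`point = "median_curve"`); the median of the per-draw
#' optima is available as an alternative. Draws with `M = 0` have no
#' optimum and are excluded with a count. The shift is modern minus
#' historical, draw-matched.
#'
#' @param fit an `nmix_fit`.
#' @param grid elevation grid.
#' @param point point-estimate convention.
#' @return List: `optimum` (named point estimates per period), `hdi`
#'   (period x c(lower, upper) matrix over per-draw optima), `draws`
#'   (data.frame `opt_hist`, `opt_mod`, `shift`), `shift` (named vector
#'   `point`, `median`, `hdi_lo`, `hdi_hi`), `n_excluded`.
#' @export
optimum_shift <- function(fit, grid = elevation_grid(),
                          point = c("median_curve", "draw_median")) {
  stopifnot(inherits(fit, "nmix_fit"))
  point <- match.arg(point)
  prof <- list(historical = profile_from_draws(fit, "historical", grid),
               modern = profile_from_draws(fit, "modern", grid))
  opt_draws <- lapply(prof, function(pr) {
    o <- grid[max.col(pr$lambda, ties.method = "first")]
    o[apply(pr$lambda, 1, max) <= 0] <- NA_real_
    o
  })
  n_excl <- sum(is.na(opt_draws$historical) | is.na(opt_draws$modern))
  pt <- vapply(prof, function(pr) grid[which.max(pr$median)], numeric(1))
  if (point == "draw_median")
    pt <- vapply(opt_draws, function(o) stats::median(o, na.rm = TRUE), numeric(1))
  hd <- t(vapply(opt_draws, hdi, numeric(2)))
  colnames(hd) <- c("lower", "upper")
  shift_draws <- opt_draws$modern - opt_draws$historical
  sh_hdi <- hdi(shift_draws)
  list(optimum = pt, hdi = hd,
       draws = data.frame(opt_hist = opt_draws$historical,
                          opt_mod = opt_draws$modern, shift = shift_draws),
       shift = c(point = unname(pt["modern"] - pt["historical"]),
                 median = stats::median(shift_draws, na.rm = TRUE),
                 hdi_lo = sh_hdi[1], hdi_hi = sh_hdi[2]),
       n_excluded = n_excl)
}

#' Elevational range category from historical limits
#'
#' Classifies a species as `broad` (range limits reach both ends of the
#' gradient, within a tolerance), `low` (only the lower end is reached:
#' the species has an upper range limit), or `high` (only the upper end).
#' A range detached from both gradient ends is reported as `interior` with
#' a warning (the motivating study found no such species); an empty range
#' is `uncategorized`.
#'
#' @param limits `c(low_m, high_m)` from [range_limits].
#' @param grid_bounds `c(min, max)` of the gradient.
#' @param tol_m tolerance in meters for "touching" a gradient end.
#' @return Character scalar.
#' @export
categorize_range <- function(limits, grid_bounds = c(201, 1443), tol_m = 25) {
  if (any(is.na(limits))) return("uncategorized")
  lo_touch <- limits[1] <= grid_bounds[1] + tol_m
  hi_touch <- limits[2] >= grid_bounds[2] - tol_m
  if (lo_touch && hi_touch) return("broad")
  if (lo_touch) return("low")
  if (hi_touch) return("high")
  warning("range detached from both gradient ends (interior species)")
  "interior"
}

#' Rule-based response scenario
#'
#' Deterministic formalization of the six response scenarios used to
#' summarize two-period abundance change: `stable`, `abundance_expansion_up`,
#' `abundance_shift_up`, `high_elevation_contraction`, `decline`,
#' `abundance_expansion_down`. Rules operate on the per-elevation classes
#' from [classify_elevation_change] within the union of the two ranges,
#' split into lower/middle/upper thirds of the historical range:
#' \itemize{
#' \item all elevations stable -> `stable`;
#' \item gains (increase or expansion) in the upper third together with
#'   losses (decrease or contraction) in the lower third ->
#'   `abundance_shift_up`;
#' \item losses in the lower third of a high-elevation species ->
#'   `high_elevation_contraction`;
#' \item gains in the upper third with no losses in the lower two-thirds ->
#'   `abundance_expansion_up`; the mirrored rule -> `abundance_expansion_down`;
#' \item losses over more than half of the range -> `decline`.
#' }
#' When several rules match, precedence is shift_up > contraction >
#' expansion_up > expansion_down > decline > stable, and the conflict is
#' reported via attribute `"conflict"`. When none match but changes exist,
#' the label falls back to the side (up/down/decline) holding the majority
#' of changed elevations.
#'
#' @param classes factor from [classify_elevation_change].
#' @param grid elevation grid the classes live on.
#' @param range_category historical range category from [categorize_range].
#' @return Scenario label (character scalar), with attribute `conflict`
#'   (logical) when more than one rule matched.
#' @export
assign_scenario <- function(classes, grid, range_category = "broad") {
  stopifnot(length(classes) == length(grid))
  lim <- attr(classes, "limits_hist")
  inside <- which(classes != "outside")
  if (!length(inside) || all(classes[inside] == "stable")) return("stable")
  ref <- if (!is.null(lim) && !any(is.na(lim))) lim else range(grid[inside])
  thirds <- ref[1] + diff(ref) * c(1, 2) / 3
  gain <- classes %in% c("increase", "range_expansion")
  loss <- classes %in% c("decrease", "range_contraction")
  lower <- grid <= thirds[1]
  upper <- grid >= thirds[2]
  ok <- rep(FALSE, 5)
  names(ok) <- c("abundance_shift_up", "high_elevation_contraction",
                 "abundance_expansion_up", "abundance_expansion_down", "decline")
  ok["abundance_shift_up"] <- any(gain & upper) && any(loss & lower)
  ok["high_elevation_contraction"] <- range_category == "high" && any(loss & lower)
  ok["abundance_expansion_up"] <- any(gain & upper) && !any(loss & !upper)
  ok["abundance_expansion_down"] <- any(gain & lower) && !any(loss & !lower)
  ok["decline"] <- sum(loss[inside]) > 0.5 * length(inside)
  if (!any(ok)) {
    n_up <- sum(gain & upper); n_down <- sum(gain & lower)
    lab <- if (any(loss) && sum(loss) >= sum(gain)) "decline"
    else if (n_up >= n_down) "abundance_expansion_up"
    else "abundance_expansion_down"
    return(lab)
  }
  lab <- names(ok)[which(ok)[1]]
  attr(lab, "conflict") <- sum(ok) > 1
  lab
}

#' Cross-species mean shift with uncertainty
#'
#' Averages per-species posterior shift draws across species, draw-matched:
#' for every retained draw the mean of the species' shifts is formed, and
#' that mean is summarized by its median and 89% HDI. A bootstrap over the
#' species' point shifts is available as an alternative uncertainty
#' convention. Species absent from the data but named in `exclude` raise an
#' error.
#'
#' @param shift_draws named list (or draws x species matrix) of per-species
#'   posterior shift draws, equal lengths.
#' @param exclude species codes to leave out (e.g. species absent or nearly
#'   absent in one period).
#' @param method `"draws"` (posterior propagation) or `"bootstrap"`
#'   (resampling species' point shifts).
#' @param n_boot bootstrap replicates.
#' @return List: `mean` (point estimate: median of the draw-wise mean, or
#'   mean of point shifts under bootstrap), `hdi`, `point_shifts` (named
#'   per-species medians), `range` of point shifts, `n_species`.
#' @export
mean_shift_across_species <- function(shift_draws, exclude = character(0),
                                      method = c("draws", "bootstrap"),
                                      n_boot = 2000) {
  method <- match.arg(method)
  if (is.matrix(shift_draws))
    shift_draws <- as.list(as.data.frame(shift_draws))
  unknown <- setdiff(exclude, names(shift_draws))
  if (length(unknown))
    stop("exclusion of unknown species code(s): ", paste(unknown, collapse = ", "))
  shift_draws <- shift_draws[setdiff(names(shift_draws), exclude)]
  if (length(shift_draws) < 2) stop("need at least two included species")
  if (length(unique(lengths(shift_draws))) != 1)
    stop("species have unequal numbers of draws")
  pts <- vapply(shift_draws, function(v) stats::median(v, na.rm = TRUE), numeric(1))
  if (method == "draws") {
    m <- rowMeans(do.call(cbind, shift_draws), na.rm = TRUE)
    list(mean = stats::median(m), hdi = hdi(m), point_shifts = pts,
         range = range(pts), n_species = length(pts))
  } else {
    bm <- vapply(seq_len(n_boot), function(i)
      mean(sample(pts, replace = TRUE)), numeric(1))
    list(mean = mean(pts),
         hdi = unname(stats::quantile(bm, c(0.055, 0.945))), point_shifts = pts,
         range = range(pts), n_species = length(pts))
  }
}
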