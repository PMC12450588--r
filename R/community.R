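#' Community total abundance across elevation
#'
#' Sums expected abundance across species at every elevation, separately
#' for every retained posterior draw, then summarizes by the median and 89%
#' HDI. All profiles must share the grid and the number of draws
#' (draw-matched propagation).
#'
#' @param profiles list of `abundance_profile`s (one period).
#' @param exclude species codes to leave out.
#' @return An object of class `community_curve`: `metric`
#'   (`"total_abundance"`), `grid_m`, `draws` (draw x elevation matrix),
#'   `median`, `hdi`, `included_species`.
#' @export
community_abundance <- function(profiles, exclude = character(0)) {
  profiles <- check_profiles(profiles, exclude)
  tot <- Reduce(`+`, lapply(profiles, `[[`, "lambda"))
  community_curve("total_abundance", profiles[[1]]$grid_m, tot, names(profiles))
}

#' Community species richness across elevation
#'
#' Expected richness with full posterior propagation: for every draw,
#' elevation and species, a Poisson abundance is drawn from that draw's
#' expected abundance, converted to presence/absence, and presences are
#' summed across species. Per-draw richness values are integers bounded by
#' the species count. A seed is mandatory: the Poisson draws are the only
#' randomness downstream of the fits.
#'
#' @param profiles list of `abundance_profile`s (one period).
#' @param seed integer seed for the Poisson draws.
#' @param exclude species codes to leave out.
#' @return A `community_curve` with metric `"richness"`.
#' @export
community_richness <- function(profiles, seed, exclude = character(0)) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  profiles <- check_profiles(profiles, exclude)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  dm <- dim(profiles[[1]]$lambda)
  rich <- matrix(0L, dm[1], dm[2])
  for (pr in profiles) {
    draws <- matrix(stats::rpois(length(pr$lambda), pr$lambda), dm[1], dm[2])
    rich <- rich + (draws > 0L)
  }
  community_curve("richness", profiles[[1]]$grid_m, rich, names(profiles))
}

#' Analytic expected richness (cross-check)
#'
#' Under the Poisson abundance model the probability a species is present
#' is \eqn{1 - e^{-\lambda}}; summing over species gives the expectation of
#' the simulated richness of [community_richness] without Monte-Carlo
#' noise. Provided as a cross-check, not as the headline estimator.
#'
#' @inheritParams community_abundance
#' @return A `community_curve` with metric `"richness_expected"` (per-draw
#'   expected richness; not integer-valued).
#' @export
community_richness_expected <- function(profiles, exclude = character(0)) {
  profiles <- check_profiles(profiles, exclude)
  er <- Reduce(`+`, lapply(profiles, function(pr) 1 - exp(-pr$lambda)))
  community_curve("richness_expected", profiles[[1]]$grid_m, er, names(profiles))
}

#' Sensitivity of community curves to irruptive species
#'
#' Recomputes a community curve with and without a set of irruptive species
#' (finches whose numbers fluctuate among years independently of local
#' conditions), and reports the pointwise difference of the median curves.
#'
#' @param profiles list of `abundance_profile`s (one period).
#' @param irruptive_set species codes to drop in the sensitivity run;
#'   defaults to the irruptive finches of the emulated study community
#'   (Pine Siskin, Red Crossbill, Evening Grosbeak).
#' @param metric `"total_abundance"` or `"richness"`.
#' @param seed required when `metric = "richness"`.
#' @return List `with`, `without` (two `community_curve`s) and
#'   `median_difference` (with minus without, per elevation).
#' @export
irruptive_sensitivity <- function(profiles,
                                  irruptive_set = c("PISI", "RECR", "EVGR"),
                                  metric = c("total_abundance", "richness"),
                                  seed = NULL) {
  metric <- match.arg(metric)
  present <- names(profiles)
  unknown <- setdiff(irruptive_set, present)
  if (length(unknown))
    stop("irruptive species not among the modeled set: ",
         paste(unknown, collapse = ", "))
  run <- function(excl) {
    if (metric == "total_abundance") community_abundance(profiles, exclude = excl)
    else {
      if (is.null(seed)) stop("richness sensitivity needs a seed")
      community_richness(profiles, seed = seed, exclude = excl)
    }
  }
  with_all <- run(character(0))
  without <- run(irruptive_set)
  list(with = with_all, without = without,
       median_difference = with_all$median - without$median)
}

check_profiles <- function(profiles, exclude) {
  if (is.null(names(profiles)) || any(names(profiles) == ""))
    names(profiles) <- vapply(profiles, `[[`, character(1), "species_code")
  unknown <- setdiff(exclude, names(profiles))
  if (length(unknown))
    stop("excluded species not among the profiles: ", paste(unknown, collapse = ", "))
  profiles <- profiles[setdiff(names(profiles), exclude)]
  if (!length(profiles)) stop("no profiles left")
  g <- profiles[[1]]$grid_m
  nd <- nrow(profiles[[1]]$lambda)
  for (pr in profiles) {
    if (!isTRUE(all.equal(pr$grid_m, g))) stop("profiles are on different grids")
    if (nrow(pr$lambda) != nd) stop("profiles have different draw counts")
  }
  profiles
}

community_curve <- function(metric, grid, draws, included) {
  med <- apply(draws, 2, stats::median)
  hd <- t(apply(draws, 2, hdi))
  colnames(hd) <- c("lower", "upper")
  structure(list(metric = metric, grid_m = grid, draws = draws,
                 median = med, hdi = hd, included_species = included),
            class = "community_curve")
}

#' @export
print.community_curve <- function(x, ...) {
  cat(sprintf("Community %s curve: %d elevations, %d draws, %d species\n",
              x$metric, length(x$grid_m), nrow(x$draws),
              length(x$included_species)))
  invisible(x)
}
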