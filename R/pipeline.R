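#' Per-species change summary
#'
#' Runs the full derivation chain for one fitted species: abundance
#' profiles for both periods, optimum elevations with 89% HDIs and their
#' shift, range limits and their shifts, per-elevation change classes, the
#' historical range category, the response scenario, and the
#' identifiability flag.
#'
#' @param fit an `nmix_fit`.
#' @param grid elevation grid.
#' @param rule a [range_rule].
#' @return List with `summary` (one-row data.frame), `classes`
#'   (per-elevation factor), `profiles` (historical and modern), and
#'   `shift_draws` (per-draw optimum shifts, for cross-species averaging).
#' @export
summarize_species_change <- function(fit, grid = elevation_grid(),
                                     rule = range_rule()) {
  stopifnot(inherits(fit, "nmix_fit"))
  ph <- profile_from_draws(fit, "historical", grid)
  pm <- profile_from_draws(fit, "modern", grid)
  cls <- classify_elevation_change(ph, pm, rule)
  lim_h <- attr(cls, "limits_hist")
  lim_m <- attr(cls, "limits_mod")
  os <- optimum_shift(fit, grid)
  cat_h <- suppressWarnings(categorize_range(lim_h, range(grid)))
  scen <- assign_scenario(cls, grid, cat_h)
  ident <- assess_identifiability(fit, grid)
  summary <- data.frame(
    species_code = fit$species_code,
    optimum_hist_m = os$optimum[["historical"]],
    optimum_hist_lo = os$hdi["historical", "lower"],
    optimum_hist_hi = os$hdi["historical", "upper"],
    optimum_mod_m = os$optimum[["modern"]],
    optimum_mod_lo = os$hdi["modern", "lower"],
    optimum_mod_hi = os$hdi["modern", "upper"],
    optimum_shift_m = os$shift[["point"]],
    low_limit_hist_m = lim_h[["low_m"]], high_limit_hist_m = lim_h[["high_m"]],
    low_limit_mod_m = lim_m[["low_m"]], high_limit_mod_m = lim_m[["high_m"]],
    low_limit_shift_m = lim_m[["low_m"]] - lim_h[["low_m"]],
    high_limit_shift_m = lim_m[["high_m"]] - lim_h[["high_m"]],
    range_category = cat_h,
    scenario = as.character(scen),
    identifiability = ident$flag,
    max_rhat = ident$max_rhat,
    stringsAsFactors = FALSE)
  list(summary = summary, classes = cls,
       profiles = list(historical = ph, modern = pm),
       shift_draws = os$draws$shift)
}

#' Run the whole analysis pipeline
#'
#' Orchestrates filter -> fit -> derive -> community on a survey table and
#' writes all stage outputs plus a reproducibility manifest to a directory.
#' Cross-species means are taken over species flagged well-defined, after
#' auto-excluding species whose modeled range is empty in either period
#' (species absent or nearly absent from one era cannot contribute a
#' meaningful shift).
#'
#' @param records validated survey records (or a CSV path readable by
#'   [read_survey_csv]).
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for the fits and the richness draws.
#' @param filter_cfg a [filter_config].
#' @param control an [nmix_control].
#' @param grid elevation grid for all derived quantities.
#' @param rule a [range_rule].
#' @param run_community also compute community abundance and richness
#'   curves (default `TRUE`).
#' @return Invisibly, a list with `summaries` (per-species data.frame),
#'   `mean_shifts`, `fits`, `community` and the manifest; the same content
#'   is written as CSV/JSON under `out_dir`.
#' @export
run_pipeline <- function(records, out_dir, seed,
                         filter_cfg = filter_config(),
                         control = nmix_control(),
                         grid = elevation_grid(),
                         rule = range_rule(),
                         run_community = TRUE) {
  if (is.character(records)) records <- read_survey_csv(records)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  filtered <- filter_surveys(records, filter_cfg)
  removals <- attr(filtered, "removals")
  stations <- unique(filtered[, c("station_id", "elevation_m")])
  std <- elev_standardizer(stations$elevation_m)
  cms <- build_count_matrices(filtered)

  set.seed(seed)
  fit_seeds <- sample.int(.Machine$integer.max, length(cms))
  fits <- list(); summaries <- list(); shift_draws <- list(); classes <- list()
  profiles_h <- list(); profiles_m <- list()
  for (i in seq_along(cms)) {
    sp <- names(cms)[i]
    set.seed(fit_seeds[i])
    fit <- tryCatch(fit_species(cms[[i]], std, control = control),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      message("fit failed for ", sp, ": ", conditionMessage(fit))
      next
    }
    fits[[sp]] <- fit
    ch <- summarize_species_change(fit, grid, rule)
    summaries[[sp]] <- ch$summary
    shift_draws[[sp]] <- ch$shift_draws
    classes[[sp]] <- ch$classes
    profiles_h[[sp]] <- ch$profiles$historical
    profiles_m[[sp]] <- ch$profiles$modern
  }
  if (!length(summaries)) stop("no species could be fitted")
  summary_df <- do.call(rbind, summaries)
  rownames(summary_df) <- NULL

  empty_range <- is.na(summary_df$low_limit_hist_m) | is.na(summary_df$low_limit_mod_m)
  well <- summary_df$identifiability == "well_defined" & !empty_range
  mean_shifts <- NULL
  if (sum(well) >= 2)
    mean_shifts <- mean_shift_across_species(shift_draws[summary_df$species_code[well]])

  community <- NULL
  if (run_community) {
    community <- list(
      abundance = list(historical = community_abundance(profiles_h),
                       modern = community_abundance(profiles_m)),
      richness = list(historical = community_richness(profiles_h, seed = seed + 1L),
                      modern = community_richness(profiles_m, seed = seed + 2L)))
  }

  manifest <- list(
    seed = seed, fit_seeds = fit_seeds,
    n_input_records = nrow(records), removals = as.list(removals),
    n_stations = nrow(stations), n_species_fit = length(fits),
    standardizer = list(center_m = std$center_m, scale_m = std$scale_m),
    grid = list(from = min(grid), to = max(grid), n = length(grid)),
    control = unclass(control), rule = unclass(rule),
    package_version = as.character(utils::packageVersion("hofnmix")))

  utils::write.csv(summary_df, file.path(out_dir, "change_summaries.csv"),
                   row.names = FALSE)
  cls_df <- do.call(rbind, lapply(names(classes), function(sp)
    data.frame(species_code = sp, elevation_m = grid,
               class = as.character(classes[[sp]]))))
  utils::write.csv(cls_df, file.path(out_dir, "elevation_classes.csv"),
                   row.names = FALSE)
  if (run_community) {
    comm_df <- do.call(rbind, lapply(c("abundance", "richness"), function(met)
      do.call(rbind, lapply(c("historical", "modern"), function(prd) {
        cc <- community[[met]][[prd]]
        data.frame(metric = cc$metric, period = prd, elevation_m = cc$grid_m,
                   median = cc$median, hdi_lower = cc$hdi[, "lower"],
                   hdi_upper = cc$hdi[, "upper"])
      }))))
    utils::write.csv(comm_df, file.path(out_dir, "community_curves.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(summaries = summary_df, mean_shifts = mean_shifts,
                 fits = fits, shift_draws = shift_draws, classes = classes,
                 profiles = list(historical = profiles_h, modern = profiles_m),
                 community = community, manifest = manifest))
}

#' Results table
#'
#' Human- and machine-readable summary of a pipeline run: per-species
#' optimum and limit shifts, the cross-species means with 89% intervals,
#' and the scenario tally.
#'
#' @param summaries per-species summary data.frame (from [run_pipeline]).
#' @param mean_shifts cross-species mean list (from
#'   [mean_shift_across_species]); optional.
#' @return data.frame (the per-species table) with attributes
#'   `scenario_tally` and `mean_shifts`; printed with both.
#' @export
results_table <- function(summaries, mean_shifts = NULL) {
  cols <- c("species_code", "optimum_hist_m", "optimum_mod_m",
            "optimum_shift_m", "low_limit_shift_m", "high_limit_shift_m",
            "range_category", "scenario", "identifiability")
  out <- summaries[, intersect(cols, names(summaries)), drop = FALSE]
  tally <- if (nrow(out)) table(out$scenario) else table(character(0))
  structure(out, scenario_tally = tally, mean_shifts = mean_shifts,
            class = c("hofnmix_results", "data.frame"))
}

#' @export
print.hofnmix_results <- function(x, ...) {
  cat("Per-species change summary\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  tally <- attr(x, "scenario_tally")
  if (length(tally)) {
    cat("\nScenario tally:\n")
    print(tally)
  }
  ms <- attr(x, "mean_shifts")
  if (!is.null(ms))
    cat(sprintf("\nMean optimum shift across %d species: %.0f m (89%% HDI %.0f to %.0f m)\n",
                ms$n_species, ms$mean, ms$hdi[1], ms$hdi[2]))
  invisible(x)
}
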