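#' Column mapping for survey tables
#'
#' Maps the canonical record fields onto the column names of an input CSV.
#' The canonical fields are: `station_id`, `elevation_m`, `period`
#' (\"historical\"/\"modern\"), `visit_date` (ISO-8601), `replicate`
#' (sub-count index within station and period), `species_code` (4-letter
#' alpha code), `count`, `distance_m`. Rows with `count = 0` record survey
#' effort with no detection and are legitimate.
#'
#' @param ... `field = "column name"` overrides.
#' @return Named character vector, canonical field -> file column.
#' @export
survey_schema <- function(...) {
  schema <- c(station_id = "station_id", elevation_m = "elevation_m",
              period = "period", visit_date = "visit_date",
              replicate = "replicate", species_code = "species_code",
              count = "count", distance_m = "distance_m")
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(schema))
    if (length(bad)) stop("unknown schema field(s): ", paste(bad, collapse = ", "))
    schema[names(ov)] <- ov
  }
  schema
}

#' Read and validate a point-count survey table
#'
#' Reads a comma-separated survey file, renames columns through the schema,
#' and validates every row. Malformed rows are reported with their row
#' numbers (header excluded) and abort the read.
#'
#' @param path CSV file with a header row.
#' @param schema a [survey_schema] mapping.
#' @return A `data.frame` of validated survey records with canonical column
#'   names; `period` is a factor with levels `historical`, `modern`.
#' @export
read_survey_csv <- function(path, schema = survey_schema()) {
  if (!file.exists(path)) stop("survey file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(schema), names(raw))
  if (length(missing_cols))
    stop("survey file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  rec <- raw[, unname(schema)]
  names(rec) <- names(schema)
  validate_survey_records(rec)
}

#' Validate survey records
#'
#' Enforces the record invariants: counts are non-negative integers,
#' elevations positive, distances non-negative, periods drawn from
#' historical/modern, dates parseable. Problems are reported with row
#' numbers.
#'
#' @param rec data.frame with canonical columns (see [survey_schema]).
#' @return The validated data.frame (period as factor, visit_date as Date).
#' @export
validate_survey_records <- function(rec) {
  need <- names(survey_schema())
  missing_cols <- setdiff(need, names(rec))
  if (length(missing_cols))
    stop("records are missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  problems <- character(0)
  flag <- function(bad, what) {
    if (any(bad)) problems <<- c(problems, sprintf(
      "%s in row(s) %s", what, paste(utils::head(which(bad), 5L), collapse = ", ")))
  }
  cnt <- suppressWarnings(as.numeric(rec$count))
  flag(is.na(cnt) | cnt < 0 | cnt != floor(cnt), "count is not a non-negative integer")
  elev <- suppressWarnings(as.numeric(rec$elevation_m))
  flag(is.na(elev) | elev <= 0, "elevation_m is not a positive number")
  dst <- suppressWarnings(as.numeric(rec$distance_m))
  flag(is.na(dst) | dst < 0, "distance_m is not a non-negative number")
  flag(!(rec$period %in% c("historical", "modern")),
       "period is not 'historical' or 'modern'")
  dt <- as.Date(as.character(rec$visit_date), format = "%Y-%m-%d")
  flag(is.na(dt), "visit_date is not an ISO-8601 date")
  rep_k <- suppressWarnings(as.numeric(rec$replicate))
  flag(is.na(rep_k) | rep_k < 1 | rep_k != floor(rep_k),
       "replicate is not a positive integer")
  if (length(problems)) stop(paste(problems, collapse = "; "))
  rec$count <- as.integer(cnt)
  rec$elevation_m <- elev
  rec$distance_m <- dst
  rec$replicate <- as.integer(rep_k)
  rec$visit_date <- dt
  rec$period <- factor(rec$period, levels = c("historical", "modern"))
  rec
}

#' Filtering rules for a two-period resurvey
#'
#' @param earliest_historical_date month-day cutoff (`"05-23"`): historical
#'   surveys before this date in any year are removed (they may contain
#'   migrants rather than breeders). Applies to the historical period only.
#' @param max_distance_m detections farther than this are removed
#'   (default 75 m); the field convention codes \">75 m\" as 80 m.
#' @param distance_exempt_species species codes exempt from the distance rule
#'   (default Sooty Grouse, `"SOGR"`, whose booming display carries far
#'   beyond 75 m and is reliably detected).
#' @param stations_both_periods_only keep only stations surveyed in both
#'   periods (default `TRUE`).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(earliest_historical_date = "05-23",
                          max_distance_m = 75,
                          distance_exempt_species = "SOGR",
                          stations_both_periods_only = TRUE) {
  stopifnot(max_distance_m > 0,
            grepl("^[0-9]{2}-[0-9]{2}$", earliest_historical_date))
  structure(list(earliest_historical_date = earliest_historical_date,
                 max_distance_m = max_distance_m,
                 distance_exempt_species = distance_exempt_species,
                 stations_both_periods_only = isTRUE(stations_both_periods_only)),
            class = "filter_config")
}

#' Filter survey records for cross-period comparability
#'
#' Applies, in order: the early-season cutoff to historical rows, the
#' distance truncation to detection rows (zero-count effort rows are always
#' retained so effort is preserved), and the both-periods station rule.
#' Removal counts by reason are attached as attribute `"removals"`.
#'
#' @param rec validated survey records.
#' @param cfg a [filter_config].
#' @return Filtered records with a `removals` attribute (named integer
#'   vector of dropped row counts per reason code).
#' @export
filter_surveys <- function(rec, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  removals <- c(early_historical = 0L, beyond_distance = 0L,
                station_not_in_both_periods = 0L)
  if (nrow(rec)) {
    md <- format(rec$visit_date, "%m-%d")
    early <- rec$period == "historical" & md < cfg$earliest_historical_date
    removals["early_historical"] <- sum(early)
    rec <- rec[!early, , drop = FALSE]
  }
  if (nrow(rec)) {
    far <- rec$count > 0 & rec$distance_m > cfg$max_distance_m &
      !(rec$species_code %in% cfg$distance_exempt_species)
    removals["beyond_distance"] <- sum(far)
    rec <- rec[!far, , drop = FALSE]
  }
  if (cfg$stations_both_periods_only && nrow(rec)) {
    by_per <- split(rec$station_id, rec$period)
    both <- intersect(unique(by_per$historical), unique(by_per$modern))
    drop <- !(rec$station_id %in% both)
    removals["station_not_in_both_periods"] <- sum(drop)
    rec <- rec[!drop, , drop = FALSE]
  }
  if (!nrow(rec)) warning("no survey records remain after filtering")
  rownames(rec) <- NULL
  attr(rec, "removals") <- removals
  rec
}

#' Build per-species replicate-count matrices
#'
#' Converts filtered records into the station x replicate count arrays the
#' N-mixture model consumes, one pair of matrices (historical, modern) per
#' species. Survey effort (which station-replicates were surveyed) is taken
#' from the distinct station/period/visit/replicate combinations across
#' *all* records including zero-count rows, so a species that went
#' undetected at a surveyed replicate receives an explicit zero, never a
#' gap. Replicate numbers may differ between stations and periods; short
#' rows are padded with `NA` (meaning "not surveyed", distinct from zero).
#'
#' @param rec filtered survey records.
#' @param replicate_unit `"subcount"` keeps each (possibly aggregated)
#'   sub-count as a replicate; `"visit"` pools all sub-counts of a visit into
#'   one replicate.
#' @param modern_replicates_per_subcount when the modern rows were recorded
#'   at a finer split than the historical sub-count (e.g. 2-min halves of a
#'   4-min sub-count), the number of consecutive modern replicates to sum
#'   into one comparable sub-count (default 1 = rows already at the common
#'   unit).
#' @param species optional character vector restricting/ordering the species
#'   set; defaults to every species detected at least once.
#' @return A named list (one element per species) of class
#'   `count_matrix_set`: `species_code`, and `periods`, itself a named list
#'   with `y` (station x replicate integer matrix, `NA`-padded),
#'   `station_id` and `elevation_m` aligned to rows.
#' @export
build_count_matrices <- function(rec,
                                 replicate_unit = c("subcount", "visit"),
                                 modern_replicates_per_subcount = 1L,
                                 species = NULL) {
  replicate_unit <- match.arg(replicate_unit)
  stopifnot(modern_replicates_per_subcount >= 1L)
  if (!nrow(rec)) stop("no records to build count matrices from")

  rec$unit <- rec$replicate
  if (modern_replicates_per_subcount > 1L) {
    m <- rec$period == "modern"
    rec$unit[m] <- (rec$replicate[m] - 1L) %/% as.integer(modern_replicates_per_subcount) + 1L
  }
  if (replicate_unit == "visit") {
    # one replicate per (station, period, visit date): rank of the date
    rec$unit <- as.integer(stats::ave(
      as.numeric(rec$visit_date), rec$station_id, rec$period,
      FUN = function(v) match(v, sort(unique(v)))))
  }

  effort <- unique(rec[, c("station_id", "period", "visit_date", "unit", "elevation_m")])
  effort <- unique(effort[, c("station_id", "period", "unit", "elevation_m")])

  observed <- sort(unique(rec$species_code[rec$count > 0]))
  if (is.null(species)) species <- observed
  never <- setdiff(species, observed)
  if (length(never)) {
    message("excluding species observed in neither period: ",
            paste(never, collapse = ", "))
    species <- setdiff(species, never)
  }
  if (!length(species)) stop("no species with at least one detection")

  out <- lapply(species, function(sp) {
    per_list <- lapply(c("historical", "modern"), function(prd) {
      eff <- effort[effort$period == prd, , drop = FALSE]
      if (!nrow(eff)) return(NULL)
      stations <- sort(unique(eff$station_id))
      kmax <- max(tapply(eff$unit, eff$station_id, function(u) length(unique(u))))
      y <- matrix(NA_integer_, nrow = length(stations), ncol = kmax,
                  dimnames = list(stations, NULL))
      sub <- rec[rec$species_code == sp & rec$period == prd, , drop = FALSE]
      cnt_key <- paste(sub$station_id, sub$unit)
      cnt <- tapply(sub$count, cnt_key, sum)
      for (si in seq_along(stations)) {
        units <- sort(unique(eff$unit[eff$station_id == stations[si]]))
        for (ui in seq_along(units)) {
          k <- paste(stations[si], units[ui])
          y[si, ui] <- if (k %in% names(cnt)) as.integer(cnt[[k]]) else 0L
        }
      }
      elev <- eff$elevation_m[match(stations, eff$station_id)]
      list(y = y, station_id = stations, elevation_m = elev)
    })
    names(per_list) <- c("historical", "modern")
    structure(list(species_code = sp, periods = per_list),
              class = "count_matrix_set")
  })
  names(out) <- species
  out
}
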