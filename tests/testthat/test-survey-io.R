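test_that("read_survey_csv reads well-formed files and reports bad rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(station_id = c("A", "A", "B"), elevation_m = c(500, 500, 900),
                   period = c("historical", "modern", "modern"),
                   visit_date = c("1991-06-01", "2023-06-10", "2023-06-11"),
                   replicate = c(1, 1, 2), species_code = "PAWR",
                   count = c(2, 0, 1), distance_m = c(30, 0, 55))
  write.csv(df, f, row.names = FALSE)
  rec <- read_survey_csv(f)
  expect_equal(nrow(rec), 3)
  expect_s3_class(rec$visit_date, "Date")
  expect_equal(levels(rec$period), c("historical", "modern"))

  df_bad <- df; df_bad$count[2] <- -1
  write.csv(df_bad, f, row.names = FALSE)
  expect_error(read_survey_csv(f), "count.*row\\(s\\) 2")

  df_nocol <- df[, setdiff(names(df), "distance_m")]
  write.csv(df_nocol, f, row.names = FALSE)
  expect_error(read_survey_csv(f), "missing required column.*distance_m")
})

test_that("schema remapping renames columns and rejects unknown fields", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(pt = "A", elev = 500, era = "modern", date = "2023-06-10",
                   sub = 1, sp = "PAWR", n = 1, dist = 20)
  write.csv(df, f, row.names = FALSE)
  rec <- read_survey_csv(f, survey_schema(
    station_id = "pt", elevation_m = "elev", period = "era",
    visit_date = "date", replicate = "sub", species_code = "sp",
    count = "n", distance_m = "dist"))
  expect_equal(rec$station_id, "A")
  expect_error(survey_schema(bogus = "x"), "unknown schema field")
})

test_that("filter_surveys applies the three removal rules", {
  rec <- make_records(
    rec_row(station = "A", period = "historical", date = "1991-05-10"), # early
    rec_row(station = "A", period = "historical", date = "1991-05-23"),
    rec_row(station = "A", period = "modern", date = "2023-05-10"),     # modern: no cutoff
    rec_row(station = "A", period = "modern", species = "PAWR", distance = 80),
    rec_row(station = "A", period = "modern", species = "SOGR", distance = 80),
    rec_row(station = "B", period = "historical", date = "1991-06-01"))  # one period only
  out <- filter_surveys(rec)
  rm <- attr(out, "removals")
  expect_equal(unname(rm["early_historical"]), 1L)
  expect_equal(unname(rm["beyond_distance"]), 1L)       # PAWR removed, SOGR kept
  expect_equal(unname(rm["station_not_in_both_periods"]), 1L)
  expect_false(any(out$station_id == "B"))
  expect_true(any(out$species_code == "SOGR" & out$distance_m == 80))
  expect_equal(nrow(rec) - nrow(out), sum(rm))  # every removal attributable
})

test_that("zero-count effort rows survive the distance filter", {
  rec <- make_records(
    rec_row(station = "A", period = "historical", count = 0, distance = 80),
    rec_row(station = "A", period = "modern", count = 0, distance = 80))
  out <- filter_surveys(rec)
  expect_equal(nrow(out), 2)
})

test_that("filtering is idempotent and tolerates empty input", {
  rec <- make_records(
    rec_row(station = "A", period = "historical"),
    rec_row(station = "A", period = "modern"),
    rec_row(station = "B", period = "historical", date = "1991-05-01"))
  once <- filter_surveys(rec)
  twice <- suppressWarnings(filter_surveys(once))
  attr(once, "removals") <- NULL; attr(twice, "removals") <- NULL
  expect_identical(once, twice)
  empty <- rec[0, , drop = FALSE]
  expect_warning(out <- filter_surveys(empty), "no survey records")
  expect_equal(nrow(out), 0)
})

test_that("count matrices zero-fill surveyed effort and stay ragged", {
  rec <- make_records(
    # station A: 3 historical replicates, 2 modern; B: 2 and 2
    rec_row("A", 400, "historical", "1991-06-01", 1, "XAAA", 1, 10),
    rec_row("A", 400, "historical", "1991-06-01", 2, "XAAA", 0, 0),
    rec_row("A", 400, "historical", "1991-06-02", 3, "XAAA", 0, 0),
    rec_row("A", 400, "modern", "2023-06-01", 1, "XAAA", 0, 0),
    rec_row("A", 400, "modern", "2023-06-01", 2, "XAAA", 0, 0),
    rec_row("B", 900, "historical", "1991-06-03", 1, "XAAA", 0, 0),
    rec_row("B", 900, "historical", "1991-06-03", 2, "XBBB", 2, 40),
    rec_row("B", 900, "modern", "2023-06-02", 1, "XBBB", 1, 20),
    rec_row("B", 900, "modern", "2023-06-02", 2, "XAAA", 0, 0))
  cms <- build_count_matrices(rec)
  expect_setequal(names(cms), c("XAAA", "XBBB"))
  yh <- cms$XAAA$periods$historical$y
  expect_equal(dim(yh), c(2, 3))
  expect_equal(yh["A", ], c(1L, 0L, 0L))
  expect_equal(yh["B", ], c(0L, 0L, NA_integer_)) # B surveyed twice: ragged
  # species detected only at B still gets explicit zeros at A
  yb <- cms$XBBB$periods$historical$y
  expect_equal(yb["A", ], c(0L, 0L, 0L))
  # matrix totals equal record totals per species and period
  for (sp in names(cms)) for (prd in c("historical", "modern")) {
    expect_equal(sum(cms[[sp]]$periods[[prd]]$y, na.rm = TRUE),
                 sum(rec$count[rec$species_code == sp & rec$period == prd]))
  }
})

test_that("species observed nowhere are excluded with a notice", {
  rec <- make_records(
    rec_row("A", 400, "historical", "1991-06-01", 1, "XAAA", 1, 10),
    rec_row("A", 400, "modern", "2023-06-01", 1, "XAAA", 1, 10))
  expect_message(cms <- build_count_matrices(rec, species = c("XAAA", "GHOST")),
                 "GHOST")
  expect_setequal(names(cms), "XAAA")
})

test_that("replicate units aggregate to visits or paired modern sub-counts", {
  rec <- make_records(
    rec_row("A", 400, "historical", "1991-06-01", 1, "XAAA", 1, 10),
    rec_row("A", 400, "historical", "1991-06-01", 2, "XAAA", 2, 10),
    rec_row("A", 400, "historical", "1991-06-08", 3, "XAAA", 1, 10),
    rec_row("A", 400, "modern", "2023-06-01", 1, "XAAA", 1, 10),
    rec_row("A", 400, "modern", "2023-06-01", 2, "XAAA", 1, 10),
    rec_row("A", 400, "modern", "2023-06-01", 3, "XAAA", 0, 0),
    rec_row("A", 400, "modern", "2023-06-01", 4, "XAAA", 2, 10))
  # visit unit: one column per visit date, counts pooled
  cmv <- build_count_matrices(rec, replicate_unit = "visit")
  expect_equal(cmv$XAAA$periods$historical$y["A", ], c(3L, 1L))
  expect_equal(unname(cmv$XAAA$periods$modern$y["A", ]), 4L)
  # modern rows at 2-min resolution: consecutive pairs sum to 4-min sub-counts
  cm2 <- build_count_matrices(rec, modern_replicates_per_subcount = 2)
  expect_equal(cm2$XAAA$periods$modern$y["A", ], c(2L, 2L))
  expect_equal(cm2$XAAA$periods$historical$y["A", ], c(1L, 2L, 1L)) # unchanged
})
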