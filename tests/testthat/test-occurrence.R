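test_that("standardization preserves provenance and assigns fresh uids", {
  raw <- raw_occ_table(3)
  ds <- occ_standardize(raw)
  rec <- ds$records
  expect_equal(nrow(rec), 3)
  expect_equal(anyDuplicated(rec$uid), 0)
  expect_equal(rec$source_occurrence_id, raw$occurrenceID)
  expect_equal(rec$institution, raw$institutionCode)
  expect_equal(rec$catalog_number, raw$catalogNumber)
  expect_equal(rec$lat, raw$decimalLatitude)
  expect_true(all(rec$manual_flags == ""))
  # all 8 documentation fields populated
  expect_true(all(rec$doc_score == 8L))
})

test_that("doc score counts populated documentation fields", {
  raw <- raw_occ_table(1)
  raw$locality <- NA          # drop 2 of the 8 documentation fields
  raw$recordedBy <- ""
  ds <- occ_standardize(raw)
  expect_equal(ds$records$doc_score, 6L)
})

test_that("unparseable or missing coordinates flag rather than reject", {
  raw <- raw_occ_table(2)
  raw$decimalLatitude <- c("4.5", "not-a-number")
  ds <- occ_standardize(raw)
  expect_equal(nrow(ds$records), 2)
  expect_true(has_flag(ds$records$auto_flags, "MISSING_COORDS")[2])
  expect_false(ds$records$visible[2])
  expect_true(ds$records$visible[1])
})

test_that("unmappable mandatory columns are a configuration error", {
  raw <- raw_occ_table(2)
  raw$decimalLatitude <- NULL
  expect_error(occ_standardize(raw), "configuration error.*lat")
})

test_that("automated checks flag the planted error classes and are idempotent", {
  region <- square_poly(-76, 0, -70, 6)
  dem <- raster_create(matrix(rep(seq(1000, 0, length.out = 10), 10), 10, 10),
                       -76, 0, 0.6)
  raw <- raw_occ_table(7, lat = c(3, 0, 30, -72.5, 3, 3, 3),
                       lon = c(-73, 0, -73, 3, -73, -73, -73))
  # row 2: (0,0); row 3: far north outside region; row 4: lat/lon transposed
  raw$elevation[5] <- 5000                       # DEM here is ~0-1000 m
  raw[6, c("occurrenceID", "institutionCode", "collectionCode",
           "catalogNumber")] <-
    raw[1, c("occurrenceID", "institutionCode", "collectionCode",
             "catalogNumber")]
  raw$eventDate[7] <- "2999-01-01"
  ds <- occ_standardize(raw)
  ds <- occ_run_checks(ds, reference = list(region = region, dem = dem))
  f <- ds$records$auto_flags
  expect_true(has_flag(f, "ZERO_COORDS")[2])
  expect_true(has_flag(f, "OUT_OF_REGION")[2])   # (0,0) is outside too
  expect_true(has_flag(f, "OUT_OF_REGION")[3])
  expect_false(has_flag(f, "COORD_SWAP")[3])     # swap does not fix row 3
  expect_true(has_flag(f, "COORD_SWAP")[4])
  expect_true(has_flag(f, "ELEV_MISMATCH")[5])
  expect_true(has_flag(f, "DUPLICATE_EXACT")[6])
  expect_true(has_flag(f, "FUTURE_DATE")[7])
  expect_equal(sum(nzchar(f[1])), 0)             # clean record stays clean
  ds2 <- occ_run_checks(ds, reference = list(region = region, dem = dem))
  expect_identical(ds2$records, ds$records)      # idempotent
})

test_that("out-of-region flag agrees with a direct point-in-polygon oracle", {
  region <- square_poly(-75, 0, -70, 5)
  withr::with_seed(11, {
    lon <- runif(40, -80, -65)
    lat <- runif(40, -5, 10)
  })
  raw <- raw_occ_table(40, lat = lat, lon = lon)
  ds <- suppressWarnings(occ_run_checks(occ_standardize(raw),
                                        reference = list(region = region)))
  inside <- lon >= -75 & lon <= -70 & lat >= 0 & lat <= 5
  expect_equal(has_flag(ds$records$auto_flags, "OUT_OF_REGION"), !inside)
})

test_that("missing reference layers skip only the rules that need them", {
  raw <- raw_occ_table(2)
  ds <- occ_standardize(raw)
  w <- capture_warnings(occ_run_checks(ds))
  expect_true(any(grepl("OUT_OF_REGION", w)))
  expect_true(any(grepl("ELEV_MISMATCH", w)))
  expect_true(any(grepl("COORD_SWAP", w)))
  # rules with no reference requirement still ran
  out <- suppressWarnings(occ_run_checks(ds))
  expect_s3_class(out, "occ_dataset")
})

test_that("visibility is exactly the blocking-flag rule", {
  raw <- raw_occ_table(10)
  raw$decimalLatitude[c(2, 5)] <- 0
  raw$decimalLongitude[c(2, 5)] <- 0
  raw$decimalLatitude[8] <- NA
  ds <- occ_standardize(raw)
  ds <- suppressWarnings(occ_run_checks(ds))
  expect_equal(sum(ds$records$visible), 7)
  # laxer per-dataset filter: only missing coords block
  ds2 <- apply_visibility_filter(ds, blocking = "MISSING_COORDS")
  expect_equal(sum(ds2$records$visible), 9)
  expect_error(apply_visibility_filter(ds, blocking = "NOT_A_FLAG"),
               "configuration error")
})

test_that("spatial dedup keeps the most documented record per 1-km cell", {
  raw <- raw_occ_table(2, lat = c(4.0001, 4.0002), lon = c(-74.0001, -74.0002))
  raw$locality[2] <- NA; raw$recordedBy[2] <- NA; raw$eventDate[2] <- NA
  ds <- occ_dedupe(occ_standardize(raw))
  expect_true(ds$records$visible[1])
  expect_false(ds$records$visible[2])
  expect_true(has_flag(ds$records$auto_flags, "SPATIAL_DUPLICATE")[2])
  # distinct cells: both stay visible
  far <- raw_occ_table(3, lat = c(4, 4.5, 5), lon = c(-74, -74.5, -75))
  ds2 <- occ_dedupe(occ_standardize(far))
  expect_true(all(ds2$records$visible))
})

test_that("dedup winners match a brute-force per-cell argmax oracle", {
  n <- 200
  withr::with_seed(21, {
    lat <- 4 + runif(n, 0, 0.05)       # ~ 6 x 6 one-km cells
    lon <- -74 + runif(n, 0, 0.05)
  })
  raw <- raw_occ_table(n, lat = lat, lon = lon)
  drop_doc <- withr::with_seed(22, sample(c(TRUE, FALSE), n, replace = TRUE))
  raw$locality[drop_doc] <- NA
  ds <- occ_dedupe(occ_standardize(raw))
  rec <- ds$records
  cs <- 1 / 120
  cell <- paste(floor((lon - floor(min(lon))) / cs),
                floor((lat - floor(min(lat))) / cs))
  expected_visible <- rep(FALSE, n)
  for (cl in unique(cell)) {
    idx <- which(cell == cl)
    win <- idx[order(-rec$doc_score[idx], rec$uid[idx])][1]
    expected_visible[win] <- TRUE
  }
  expect_equal(rec$visible, expected_visible)
  # at most one visible per cell, and dedup is idempotent
  expect_true(all(table(cell[rec$visible]) == 1))
  expect_identical(occ_dedupe(ds)$records, rec)
})

test_that("edits are logged with old and new values and recompute visibility", {
  ds <- occ_standardize(raw_occ_table(3))
  uid <- ds$records$uid[1]
  ds <- occ_edit(ds, uid, "lon", -74.2, actor = "curator-a")
  expect_equal(nrow(ds$audit), 1)
  expect_equal(ds$audit$field, "lon")
  expect_equal(jsonlite::fromJSON(ds$audit$old_value), -74)
  expect_equal(jsonlite::fromJSON(ds$audit$new_value), -74.2)
  expect_equal(ds$records$lon[1], -74.2)
  # a blocking manual flag hides the record
  ds <- occ_edit(ds, uid, "manual_flags", "SUSPECT_ID", actor = "curator-b")
  expect_false(ds$records$visible[1])
  expect_error(occ_edit(ds, uid, "uid", "nope", actor = "x"), "not editable")
  expect_error(occ_edit(ds, uid, "institution", "nope", actor = "x"),
               "not editable")
  expect_error(occ_edit(ds, "missing-uid", "lon", 0, actor = "x"),
               "unknown uid")
  expect_error(occ_edit(ds, uid, "manual_flags", "BOGUS", actor = "x"),
               "unknown manual flag")
})

test_that("edit then full revert is the identity on record state", {
  ds0 <- occ_standardize(raw_occ_table(4))
  uid <- ds0$records$uid[2]
  ds <- ds0
  ds <- occ_edit(ds, uid, "lat", 10.5, actor = "a")
  ds <- occ_edit(ds, uid, "lon", -70.1, actor = "a")
  ds <- occ_edit(ds, uid, "taxon", "Testus alius", actor = "b")
  ds <- occ_edit(ds, uid, "manual_flags", "GEOREF_ERROR", actor = "b")
  ds <- occ_edit(ds, uid, "lat", 11.5, actor = "c")
  expect_false(identical(ds$records, ds0$records))
  ds <- occ_revert(ds, uid)
  expect_identical(ds$records, ds0$records)
  # audit log is append-only: 5 edits + 5 compensating entries
  expect_equal(nrow(ds$audit), 10)
  expect_equal(ds$audit$entry_id, 1:10)
})

test_that("revert to the middle of an edit sequence keeps earlier edits", {
  ds <- occ_standardize(raw_occ_table(1))
  uid <- ds$records$uid[1]
  ds <- occ_edit(ds, uid, "lat", 2, actor = "a")    # entry 1
  ds <- occ_edit(ds, uid, "lat", 3, actor = "a")    # entry 2
  ds <- occ_edit(ds, uid, "lon", -70, actor = "a")  # entry 3
  ds <- occ_revert(ds, uid, to_entry_id = 2)
  expect_equal(ds$records$lat[1], 2)   # first edit retained
  expect_equal(ds$records$lon[1], -74) # third edit undone
  expect_error(occ_revert(ds, uid, to_entry_id = 99), "not found")
})

test_that("revert on an untouched record is a no-op", {
  ds <- occ_standardize(raw_occ_table(2))
  out <- occ_revert(ds, ds$records$uid[2])
  expect_identical(out$records, ds$records)
  expect_equal(nrow(out$audit), 0)
})

test_that("occurrence CSV and audit JSONL round-trip losslessly", {
  raw <- raw_occ_table(5)
  raw$decimalLatitude[3] <- 4.123456789012345
  raw$locality[2] <- NA
  ds <- occ_standardize(raw)
  ds <- suppressWarnings(occ_run_checks(ds))
  ds <- occ_edit(ds, ds$records$uid[1], "manual_flags", "OTHER", actor = "a")
  path <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(ds, path)
  back <- read_occurrences(path)
  expect_identical(back$records, ds$records)
  lpath <- withr::local_tempfile(fileext = ".jsonl")
  write_audit_log(ds, lpath)
  expect_identical(read_audit_log(lpath), ds$audit)
})
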