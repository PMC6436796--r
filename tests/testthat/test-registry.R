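test_that("the lifecycle graph only admits legal transitions", {
  rec <- model_record("m1", "Testus species")
  expect_equal(rec$status, "under_development")
  expect_error(transition(rec, "approved"), "illegal")
  rec <- transition(rec, "feedback_processed")
  expect_equal(rec$status, "pending_validation")
  # approval needs scores with a passing mean
  expect_error(transition(rec, "approved"), "at least 1 score")
  rec <- add_scores(rec, c(2, 2), reviewers = c("e1", "e2"))
  expect_error(transition(rec, "approved"), "mean expert score")
  rec <- add_scores(rec, 5, reviewers = "e3")
  rec <- transition(rec, "approved")
  expect_equal(rec$status, "validated")
  # a validated model cannot absorb feedback directly; reopen makes v2
  expect_error(transition(rec, "feedback_processed"), "illegal")
  rec <- transition(rec, "reopen")
  expect_equal(rec$status, "under_development")
  expect_equal(rec$version, 2L)
  expect_equal(nrow(rec$scores), 0)
  expect_error(transition(rec, "not_an_event"), "unknown")
  # every transition was logged
  expect_equal(vapply(rec$events, `[[`, "", "event"),
               c("feedback_processed", "approved", "reopen"))
})

test_that("no path reaches validated without a passing scoring event", {
  rec <- model_record("m2", "Testus species")
  for (ev in names(list(a = 1))) NULL
  expect_error(transition(rec, "approved"), "illegal")
  rec <- transition(rec, "feedback_processed")
  rec2 <- add_scores(rec, c(2, 3, 2))
  expect_error(transition(rec2, "approved"), "mean expert score")
  expect_equal(rec2$status, "pending_validation")
})

test_that("the mean-of-3 approval rule handles boundaries exactly", {
  expect_equal(score_and_decide(c(3, 3, 3)), "approved")
  expect_equal(score_and_decide(c(1, 5)), "approved")
  expect_equal(score_and_decide(c(2, 2, 5)), "approved")
  expect_equal(score_and_decide(c(2, 2, 4)), "pending")
  expect_error(score_and_decide(c(0, 3)), "1..5")
  expect_error(score_and_decide(c(3, 6)), "1..5")
  expect_error(score_and_decide(c(2.5, 3.5)), "1..5")
  expect_error(score_and_decide(integer()), "1..5")
})

test_that("external models publish directly only when peer reviewed", {
  meta <- list(sources = "thesis", method = "ensemble",
               methods_document = "doc.pdf")
  pub <- intake_external("ext1", "Testus species", meta, peer_reviewed = TRUE)
  expect_equal(pub$status, "published_external")
  rev <- intake_external("ext2", "Testus species", meta, peer_reviewed = FALSE)
  expect_equal(rev$status, "pending_validation")
  expect_error(intake_external("ext3", "Testus species",
                               list(sources = "x", method = "y"),
                               peer_reviewed = TRUE),
               "methods_document")
})

test_that("distribution statistics follow the IUCN range conventions", {
  bin <- raster_create(matrix(0, 20, 20), -74, 0, 0.01)
  cells <- cbind(5:14, 5:14)   # a 10-cell diagonal
  bin$values[cells] <- 1
  st <- distribution_stats(bin)
  expect_equal(st$n_cells, 10L)
  expect_equal(st$area_km2, sum(cell_area_km2(bin)[cells]))
  expect_gte(st$eoo_km2, st$area_km2)    # hull contains its points
  # single occupied cell: EOO degenerates to the cell area, AOO is one 2x2 km cell
  one <- raster_create(matrix(0, 20, 20), -74, 0, 0.01)
  one$values[3, 3] <- 1
  st1 <- distribution_stats(one)
  expect_equal(st1$eoo_km2, st1$area_km2)
  expect_equal(st1$aoo_km2, 4)
  expect_warning(st0 <- distribution_stats(raster_create(matrix(0, 5, 5),
                                                         0, 0, 1)), "empty")
  expect_equal(st0$area_km2, 0)
  # elevation range over presence cells
  dem <- raster_create(matrix(seq(100, 500, length.out = 400), 20, 20),
                       -74, 0, 0.01)
  ste <- distribution_stats(one, dem = dem)
  expect_equal(ste$elevation_range, rep(dem$values[3, 3], 2))
})

test_that("EOO equals the geodesic area of the oracle hull on random blobs", {
  withr::with_seed(61, {
    for (rep in 1:3) {
      bin <- raster_create(matrix(0, 30, 30), -74, 0, 0.01)
      bin$values[sample(900, 40)] <- 1
      st <- distribution_stats(bin)
      pres <- which(bin$values == 1)
      rc <- arrayInd(pres, dim(bin$values))
      ctr <- xy_from_cell(bin, rc[, 1], rc[, 2])
      hull_pts <- hull_oracle(ctr[, 1], ctr[, 2])
      # order oracle vertices by angle to form the ring
      cx <- mean(hull_pts[, 1]); cy <- mean(hull_pts[, 2])
      ord <- order(atan2(hull_pts[, 2] - cy, hull_pts[, 1] - cx))
      oracle_area <- abs(geosphere::areaPolygon(hull_pts[ord, ])) / 1e6
      expect_equal(st$eoo_km2, oracle_area, tolerance = 1e-6)
      expect_gte(st$eoo_km2, st$area_km2)
    }
  })
})

test_that("group summaries are exact column sums with blanks as zero", {
  tab <- expert_group_table()
  expect_equal(nrow(tab), 18)
  totals <- group_summary(tab)
  expect_equal(unname(totals["n_experts"]), 475)
  expect_equal(unname(totals["n_species"]), 980)
  expect_equal(unname(totals["n_validated"]), 78)
  # random tables agree with a brute-force double loop
  rt <- make_group_table(9, 12)
  got <- group_summary(rt)
  for (cn in names(got)) {
    acc <- 0
    for (i in seq_len(nrow(rt))) acc <- acc + rt[[cn]][i]
    expect_equal(unname(got[cn]), acc)
  }
  empty <- rt[0, ]
  expect_true(all(group_summary(empty) == 0))
  neg <- rt; neg$n_experts[1] <- -1
  expect_error(group_summary(neg), "negative")
})

test_that("model records round-trip through JSON", {
  rec <- model_record("m9", "Testus species", authors = c("a", "b"),
                      metadata = list(sources = c("gbif-export"),
                                      method = "maxent_like",
                                      settings = list(reg_multiplier = 2),
                                      seeds = list(master = 7),
                                      log_link = "https://example.org/log"))
  rec <- transition(rec, "feedback_processed")
  rec <- add_scores(rec, c(4, 3), reviewers = c("e1", "e2"))
  path <- withr::local_tempfile(fileext = ".json")
  write_model_record(rec, path)
  back <- read_model_record(path)
  expect_equal(back$model_id, rec$model_id)
  expect_equal(back$status, rec$status)
  expect_equal(back$version, rec$version)
  expect_equal(back$scores, rec$scores)
  expect_equal(back$authors, rec$authors)
  expect_equal(back$metadata$settings$reg_multiplier, 2)
  expect_equal(vapply(back$events, `[[`, "", "event"),
               vapply(rec$events, `[[`, "", "event"))
})
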