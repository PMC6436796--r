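# End-to-end workflow ----------------------------------------------------------

#' Virtual-species recovery experiment
#'
#' The standing check that the presence-background model recovers a known
#' niche: a landscape with two informative variables and one noise variable,
#' a virtual species with a strong Gaussian niche on the informative pair,
#' `n_presences` unbiased presence draws and a full background sample.
#' Held-out performance is spatial-block cross-validation (k = 4): the model
#' is refit without each block and its presences are scored against the full
#' background. Variable importance is the absolute coefficient mass of the
#' model fit on all presences.
#'
#' @param seed Integer seed.
#' @param size Landscape edge, cells.
#' @param n_presences Presence sample size.
#' @param n_background Background sample size.
#' @param features Feature classes for the fit.
#' @return List: `mean_holdout_auc`, `fold_auc`, `contributions` (named,
#'   decreasing), `informative_top` (logical: do the two niche variables
#'   carry the largest mass?).
#' @export
virtual_species_recovery <- function(seed, size = 100, n_presences = 100,
                                     n_background = 10000,
                                     features = c("linear", "quadratic",
                                                  "product", "hinge")) {
  seed <- as.integer(seed)
  full <- make_landscape(seed, size = size, n_vars = 3)
  sp <- make_species(full)
  stack <- stack_subset(full, c("env1", "env2", "env3"))
  w <- as.vector(sp$true_suitability$values)
  w[is.na(w)] <- 0
  cells <- withr::with_seed(seed + 1000L,
                            sample(length(w), n_presences, prob = w))
  rc <- arrayInd(cells, dim(stack$mask))
  ctr <- xy_from_cell(stack$grid, rc[, 1], rc[, 2])
  pres_env <- stack_extract(stack, ctr[, 1], ctr[, 2])
  bg <- sample_background(stack, n = n_background, seed = seed + 2000L)
  bg_env <- stack_extract(stack, bg$lon, bg$lat)
  blocks <- suppressWarnings(spatial_partition(ctr[, 1], ctr[, 2], k = 4))
  fold_auc <- vapply(1:4, function(f) {
    m <- fit_maxent_like(pres_env[blocks$folds != f, , drop = FALSE],
                         bg_env, features = features)
    auc_score(predict(m, pres_env[blocks$folds == f, , drop = FALSE]),
              predict(m, bg_env))
  }, 0)
  m_all <- fit_maxent_like(pres_env, bg_env, features = features)
  contrib <- sort(variable_contributions(m_all), decreasing = TRUE)
  list(mean_holdout_auc = mean(fold_auc), fold_auc = fold_auc,
       contributions = contrib,
       informative_top = all(c("env1", "env2") %in% names(contrib)[1:2]))
}

#' Run the full collaborative-modeling workflow on a synthetic scenario
#'
#' Exercises every stage against a generated landscape and virtual species:
#' occurrence standardization and automated checks, spatial deduplication,
#' thinning, method selection on the occurrence-count ladder, background
#' sampling, model fitting and spatial-block evaluation, percentile
#' thresholding, expert-feedback editing, registry scoring/validation, and
#' fact-sheet statistics. When `out_dir` is given, artifacts are written as
#' plain-text ASCII grids, CSV and JSON.
#'
#' @param seed Integer seed driving every stochastic step (landscape,
#'   sampling, corruption, thinning tie-breaks, background).
#' @param size Landscape edge length in cells.
#' @param n_occurrences Raw occurrence records to draw.
#' @param error_rates Corruption rates for [sample_occurrences()].
#' @param thin_km Thinning distance, km (exploratory choice; see vignette).
#' @param omission_percent Expert slider setting for the published binary.
#' @param n_background Background sample size.
#' @param expert_scores Credibility scores applied at validation.
#' @param out_dir Optional output directory for artifacts.
#' @return List with the dataset, model result, threshold output, edited
#'   binary, registry record and distribution statistics.
#' @export
run_pipeline <- function(seed = 1L, size = 100, n_occurrences = 100,
                         error_rates = list(zero_coords = 0.05,
                                            transposed = 0.05,
                                            duplicate = 0.05,
                                            off_range_misID = 0.05),
                         thin_km = 2, omission_percent = 10,
                         n_background = 10000,
                         expert_scores = c(4, 3, 4), out_dir = NULL) {
  seed <- as.integer(seed)
  stack <- make_landscape(seed, size = size)
  species <- make_species(stack)
  region <- geo_polygon(cbind(
    c(stack$grid$xmin, raster_xmax(stack$grid), raster_xmax(stack$grid),
      stack$grid$xmin),
    c(stack$grid$ymin, stack$grid$ymin, raster_ymax(stack$grid),
      raster_ymax(stack$grid))))
  raw <- sample_occurrences(species, n_occurrences,
                            dem = stack$layers$dem,
                            error_rates = error_rates, seed = seed + 1L)

  ds <- occ_standardize(raw)
  ds <- occ_run_checks(ds, reference = list(region = region,
                                            dem = stack$layers$dem))
  ds <- occ_dedupe(ds)
  vis <- ds$records[ds$records$visible, ]

  keep <- thin_points(vis$lon, vis$lat, thin_km, seed = seed + 2L)
  pts <- vis[keep, c("lon", "lat")]
  M <- accessible_area(species$M_true, provenance = "expert-drawn")
  # modeling only uses records inside the accessible area; stragglers outside
  # M are the residual misidentifications the expert polygon screens out
  pts <- pts[point_in_polygon(M$geometry, pts$lon, pts$lat), , drop = FALSE]
  method <- select_method(nrow(pts))
  # predictors: the environmental fields; DEM and land cover serve QC and
  # post-processing, not model fitting
  model_stack <- stack_subset(stack, grep("^env", names(stack$layers),
                                          value = TRUE))
  background <- if (method == "maxent_like") {
    sample_background(model_stack, M, n = n_background, seed = seed + 3L)
  } else NULL
  fit <- fit_final(pts, model_stack, M = M, background = background,
                   method = method, seed = seed + 3L)

  published <- if (!is.null(fit$suitability)) {
    thr <- threshold_at_percentile(fit$suitability, pts, omission_percent)
    fb <- expert_feedback(omission_percent = omission_percent,
                          habitat_classes = 1:5, reviewer = "expert-1")
    list(threshold = thr,
         binary = apply_feedback(thr$binary, fb,
                                 landcover = stack$layers$landcover))
  } else {
    list(threshold = NULL, binary = fit$binaries[["0"]])
  }

  rec <- model_record(sprintf("synthetic-%d", seed), "Virtualis exempli",
                      authors = c("core-team", "expert-1"),
                      metadata = list(method = fit$method,
                                      n_presences = nrow(pts),
                                      seeds = list(master = seed),
                                      thin_km = thin_km,
                                      omission_percent = omission_percent))
  rec <- transition(rec, "feedback_processed")
  rec <- add_scores(rec, expert_scores,
                    reviewers = paste0("expert-", seq_along(expert_scores)))
  if (score_and_decide(rec$scores$score) == "approved") {
    rec <- transition(rec, "approved")
  }
  stats <- distribution_stats(published$binary, dem = stack$layers$dem)
  rec$metadata$distribution_stats <- stats[c("area_km2", "eoo_km2",
                                             "aoo_km2")]

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(fit$suitability)) {
      write_asc(fit$suitability, file.path(out_dir, "suitability.asc"))
    }
    for (p in names(fit$binaries)) {
      write_asc(fit$binaries[[p]], file.path(out_dir,
                                             sprintf("binary_p%s.asc", p)))
    }
    write_asc(published$binary, file.path(out_dir, "published_binary.asc"))
    write_occurrences(ds, file.path(out_dir, "occurrences.csv"))
    write_audit_log(ds, file.path(out_dir, "audit.jsonl"))
    write_geojson(M$geometry, file.path(out_dir, "accessible_area.geojson"))
    write_model_record(rec, file.path(out_dir, "model_record.json"))
  }

  list(stack = stack, species = species, dataset = ds, presences = pts,
       method = method, fit = fit, threshold = published$threshold,
       published_binary = published$binary, record = rec,
       distribution_stats = stats)
}
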