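# Thresholding and expert feedback --------------------------------------------

#' Percentile training-presence threshold
#'
#' Converts a continuous suitability layer into a binary range at the p-th
#' percentile training presence: the threshold is the largest suitability
#' value observed at a training presence such that at most p% of training
#' presences fall strictly below it (p = 0 is the minimum training
#' presence). Ties at the threshold count as predicted present, so the
#' returned training omission is always <= p%.
#'
#' @param suitability An `sdm_raster` in `[0, 1]`.
#' @param presences Data.frame with `lon`, `lat` of the training presences
#'   (all on valid cells).
#' @param p Omission percentage in `[0, 30]` (the expert slider range); any
#'   real value, not just the published 0/10/20/30 steps.
#' @return List: `binary` (`sdm_raster`, 1 where suitability >= threshold),
#'   `threshold`, and `omission` (realized training omission, fraction).
#' @export
threshold_at_percentile <- function(suitability, presences, p) {
  stopifnot(p >= 0, p <= 30)
  if (!nrow(presences)) stop("empty presence set")
  s <- raster_extract(suitability, presences$lon, presences$lat)
  if (anyNA(s)) stop("training presences fall outside valid cells")
  thr <- percentile_threshold_value(s, p)
  vals <- suitability$values
  bin <- ifelse(is.na(vals), NA_real_, as.numeric(vals >= thr))
  list(binary = raster_create(bin, suitability$xmin, suitability$ymin,
                              suitability$cellsize, suitability$crs),
       threshold = thr,
       omission = omission_rate(s, thr))
}

#' Expert feedback on a binary model
#'
#' Bundle of the review inputs an expert supplies on a published model: the
#' omission-slider setting, polygons delineating over-prediction (wrongly
#' predicted present) and under-prediction (wrongly predicted absent), and
#' optionally the land-cover classes where the species is expected to
#' maintain viable populations.
#'
#' @param omission_percent Slider value in `[0, 30]`.
#' @param over_polygons,under_polygons Lists of `geo_polygon` (may be
#'   empty).
#' @param habitat_classes Vector of allowed land-cover class codes, or
#'   `NULL`.
#' @param reviewer Reviewer identifier.
#' @return An `expert_feedback` object.
#' @export
expert_feedback <- function(omission_percent = 0, over_polygons = list(),
                            under_polygons = list(), habitat_classes = NULL,
                            reviewer = "anonymous") {
  stopifnot(omission_percent >= 0, omission_percent <= 30)
  if (inherits(over_polygons, "geo_polygon")) over_polygons <- list(over_polygons)
  if (inherits(under_polygons, "geo_polygon")) under_polygons <- list(under_polygons)
  structure(list(omission_percent = omission_percent,
                 over_polygons = over_polygons,
                 under_polygons = under_polygons,
                 habitat_classes = habitat_classes, reviewer = reviewer),
            class = "expert_feedback")
}

#' Apply expert feedback to a binary model
#'
#' Edits the binary range in a fixed order: cells inside over-prediction
#' polygons are set to 0, then cells inside under-prediction polygons to 1,
#' then (when habitat classes are given) cells on disallowed land cover to
#' 0. Under-polygons are explicit expert assertions of presence and so
#' survive over-polygons, while the habitat constraint acts as a final
#' ecological veto. The operation is idempotent for fixed feedback.
#'
#' @param binary A binary `sdm_raster`.
#' @param feedback An [expert_feedback()].
#' @param landcover Categorical `sdm_raster` on the same grid (required when
#'   `habitat_classes` is set).
#' @return The edited binary `sdm_raster`.
#' @export
apply_feedback <- function(binary, feedback, landcover = NULL) {
  stopifnot(inherits(feedback, "expert_feedback"))
  vals <- binary$values
  valid <- !is.na(vals)
  stamp <- function(polys) {
    hit <- matrix(FALSE, nrow(vals), ncol(vals))
    for (pg in polys) {
      inside <- raster_cells_in_polygon(binary, pg)
      if (!any(inside)) {
        warning("feedback polygon is disjoint from the raster extent; no effect")
      }
      hit <- hit | inside
    }
    hit
  }
  if (length(feedback$over_polygons)) {
    vals[stamp(feedback$over_polygons) & valid] <- 0
  }
  if (length(feedback$under_polygons)) {
    vals[stamp(feedback$under_polygons) & valid] <- 1
  }
  if (!is.null(feedback$habitat_classes)) {
    if (is.null(landcover)) stop("habitat classes given but no landcover raster")
    if (!same_grid(landcover, binary)) {
      stop("landcover raster is not on the template grid")
    }
    bad <- !(landcover$values %in% feedback$habitat_classes)
    vals[bad & valid] <- 0
  }
  binary$values <- vals
  binary
}

#' Build an expert range map
#'
#' For species with too few records to model, experts sketch the range
#' directly: a range polygon, optionally refined by barrier polygons to
#' exclude (rivers, canyons, watersheds), an elevation band applied against
#' a DEM, and a habitat (land-cover) constraint. The output is always a
#' subset of the rasterized range polygon.
#'
#' @param range_polygon A `geo_polygon` of the broad range.
#' @param template An `sdm_raster` supplying the grid.
#' @param barrier_polygons List of `geo_polygon` to exclude, or `NULL`.
#' @param elevation_range `c(min_m, max_m)`, or `NULL`.
#' @param dem DEM `sdm_raster` (required with `elevation_range`).
#' @param habitat_classes Allowed land-cover codes, or `NULL`.
#' @param landcover Categorical `sdm_raster` (required with
#'   `habitat_classes`).
#' @return A binary `sdm_raster`.
#' @export
build_expert_map <- function(range_polygon, template, barrier_polygons = NULL,
                             elevation_range = NULL, dem = NULL,
                             habitat_classes = NULL, landcover = NULL) {
  bin <- rasterize_polygon(range_polygon, template)
  bin$values[is.na(template$values)] <- NA_real_
  if (!is.null(barrier_polygons)) {
    if (inherits(barrier_polygons, "geo_polygon")) {
      barrier_polygons <- list(barrier_polygons)
    }
    for (pg in barrier_polygons) {
      bin$values[raster_cells_in_polygon(bin, pg)] <- 0
    }
  }
  if (!is.null(elevation_range)) {
    if (is.null(dem)) stop("elevation filter requested without a DEM")
    stopifnot(length(elevation_range) == 2,
              elevation_range[1] <= elevation_range[2])
    if (!same_grid(dem, bin)) stop("DEM is not on the template grid")
    out_band <- dem$values < elevation_range[1] |
      dem$values > elevation_range[2]
    bin$values[out_band & !is.na(bin$values)] <- 0
  }
  if (!is.null(habitat_classes)) {
    if (is.null(landcover)) stop("habitat classes given but no landcover raster")
    bin <- mask_raster(bin, landcover = landcover, classes = habitat_classes)
  }
  bin
}
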