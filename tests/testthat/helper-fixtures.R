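# shared fixture builders -----------------------------------------------------

# rectangle polygon from an extent
square_poly <- function(xmin, ymin, xmax, ymax) {
  geo_polygon(cbind(c(xmin, xmax, xmax, xmin),
                    c(ymin, ymin, ymax, ymax)))
}

# constant-valued raster on a unit-degree grid near the equator
flat_raster <- function(n = 10, value = 1, xmin = -75, ymin = 0,
                        cellsize = 0.01) {
  raster_create(matrix(value, n, n), xmin, ymin, cellsize)
}

# full-extent rectangle of a raster
raster_extent_poly <- function(x) {
  square_poly(x$xmin, x$ymin, raster_xmax(x), raster_ymax(x))
}

# raw occurrence table with complete provenance
raw_occ_table <- function(n = 3, lat = NULL, lon = NULL) {
  data.frame(
    scientificName = "Testus species",
    decimalLatitude = if (is.null(lat)) seq(1, by = 0.1, length.out = n) else lat,
    decimalLongitude = if (is.null(lon)) seq(-74, by = 0.1, length.out = n) else lon,
    institutionCode = paste0("inst", seq_len(n)),
    collectionCode = "col",
    catalogNumber = sprintf("cat%03d", seq_len(n)),
    occurrenceID = sprintf("ext-%03d", seq_len(n)),
    recordedBy = "A. Person",
    eventDate = "2010-05-01",
    locality = "somewhere",
    elevation = 100 * seq_len(n),
    stringsAsFactors = FALSE)
}

# brute-force convex hull oracle: a point is a hull vertex iff it is an
# endpoint of an edge with all remaining points strictly on one side
hull_oracle <- function(lon, lat) {
  pts <- unique(cbind(lon, lat))
  n <- nrow(pts)
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    side <- sign((pts[j, 1] - pts[i, 1]) * (pts[, 2] - pts[i, 2]) -
                   (pts[j, 2] - pts[i, 2]) * (pts[, 1] - pts[i, 1]))
    side <- side[-c(i, j)]
    if (all(side >= 0) || all(side <= 0)) {
      on_hull[c(i, j)] <- TRUE
    }
  }
  pts[on_hull, , drop = FALSE]
}

# brute-force AUC: concordant pairs / total pairs, ties half
auc_oracle <- function(pres, bg) {
  total <- 0
  for (p in pres) total <- total + sum(p > bg) + 0.5 * sum(p == bg)
  total / (length(pres) * length(bg))
}

# brute-force percentile-training-presence threshold: scan candidates
threshold_oracle <- function(scores, p) {
  allowed <- floor(p / 100 * length(scores))
  cand <- sort(unique(scores))
  best <- -Inf
  for (t in cand) if (sum(scores < t) <= allowed) best <- max(best, t)
  best
}
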