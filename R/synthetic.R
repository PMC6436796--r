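# Synthetic landscapes and virtual species ------------------------------------
#
# Everything the pipeline consumes can be generated offline: smooth random
# environmental fields, a ramp DEM, categorical land cover, a virtual
# species with a known Gaussian niche, and occurrence samples with injected,
# labelled errors. Determinism: every function takes an explicit integer
# seed and uses only R's integer-state RNG.

#' @noRd
smooth_field <- function(n, sigma) {
  noise <- matrix(stats::rnorm(n * n), n, n)
  if (sigma <= 0) return(noise)
  idx <- seq_len(n)
  K <- exp(-outer(idx, idx, `-`)^2 / (2 * sigma^2))
  K <- K / rowSums(K)                # renormalized at the edges
  K %*% noise %*% t(K)
}

#' Generate a synthetic environmental stack
#'
#' Builds `n_vars` spatially autocorrelated random fields (white noise
#' smoothed by a Gaussian kernel of radius `smoothness`, rescaled to
#' `[0, 1]`), a south-to-north linear-ramp DEM (`dem`, 0-3000 m with a
#' slight west-east cross slope), and a categorical land-cover layer
#' (`landcover`, classes 1-5 from quintiles of an extra smooth field). The
#' grid is a `size` x `size` lattice of 0.01-degree cells anchored at
#' (-75, 0), i.e. roughly 1-km cells near the equator.
#'
#' @param seed Integer seed.
#' @param size Grid edge length in cells (>= 10).
#' @param n_vars Number of environmental variables (>= 1), named
#'   `env1..envk`.
#' @param smoothness Gaussian smoothing radius in cells; larger is smoother.
#' @return An `env_stack` with layers `env1..envk`, `dem`, `landcover`.
#' @export
make_landscape <- function(seed, size = 100, n_vars = 2, smoothness = 8) {
  stopifnot(size >= 10, n_vars >= 1)
  xmin <- -75; ymin <- 0; cs <- 0.01
  withr::with_seed(as.integer(seed), {
    layers <- lapply(seq_len(n_vars), function(i) {
      f <- smooth_field(size, smoothness)
      f <- (f - min(f)) / max(diff(range(f)), 1e-12)
      raster_create(f, xmin, ymin, cs)
    })
    names(layers) <- paste0("env", seq_len(n_vars))
    ramp <- matrix(rep(seq(3000, 0, length.out = size), size), size, size)
    cross <- matrix(rep(seq(0, 150, length.out = size), each = size),
                    size, size)
    layers$dem <- raster_create(ramp + cross, xmin, ymin, cs)
    lc_field <- smooth_field(size, smoothness * 1.5)
    qs <- stats::quantile(lc_field, probs = seq(0.2, 0.8, by = 0.2))
    lc <- matrix(findInterval(lc_field, qs) + 1, size, size)
    layers$landcover <- raster_create(lc, xmin, ymin, cs)
  })
  env_stack(layers)
}

#' Define a virtual species on a landscape
#'
#' True suitability is the product of per-variable Gaussian responses
#' (optimum and breadth per environmental variable), rescaled so the best
#' valid cell scores 1; the true range is the cells at or above `cutoff`.
#' The true accessible area is the bounding box of the range expanded by
#' 10% and clipped to the landscape extent.
#'
#' @param stack An `env_stack` from [make_landscape()].
#' @param niche Named list: per-variable `c(optimum, breadth)` in the
#'   variable's units. Variables not listed do not constrain the species.
#' @param cutoff Suitability cutoff in (0, 1) defining the true range.
#' @return A `virtual_species`: `niche`, `true_suitability`,
#'   `true_range` (binary rasters), `M_true` (a `geo_polygon`), `cutoff`.
#' @export
make_species <- function(stack, niche = list(env1 = c(0.7, 0.1),
                                             env2 = c(0.3, 0.1)),
                         cutoff = 0.5) {
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must be inside (0, 1)")
  missing_vars <- setdiff(names(niche), names(stack$layers))
  if (length(missing_vars)) {
    stop("niche variables not in the stack: ",
         paste(missing_vars, collapse = ", "))
  }
  suit <- matrix(1, nrow(stack$mask), ncol(stack$mask))
  for (v in names(niche)) {
    pars <- niche[[v]]
    suit <- suit * exp(-(stack$layers[[v]]$values - pars[1])^2 /
                         (2 * pars[2]^2))
  }
  suit[!stack$mask] <- NA_real_
  mx <- max(suit, na.rm = TRUE)
  if (mx > 0) suit <- suit / mx
  rng <- ifelse(is.na(suit), NA_real_, as.numeric(suit >= cutoff))
  g <- stack$grid
  pres <- which(rng == 1, arr.ind = TRUE)
  bbox <- if (nrow(pres)) {
    ctr <- xy_from_cell(g, pres[, 1], pres[, 2])
    apply(ctr, 2, range)
  } else {
    matrix(c(g$xmin, raster_xmax(g), g$ymin, raster_ymax(g)), 2)
  }
  pad <- 0.1 * pmax(bbox[2, ] - bbox[1, ], g$cellsize)
  lo <- pmax(bbox[1, ] - pad, c(g$xmin, g$ymin))
  hi <- pmin(bbox[2, ] + pad, c(raster_xmax(g), raster_ymax(g)))
  M <- geo_polygon(cbind(c(lo[1], hi[1], hi[1], lo[1]),
                         c(lo[2], lo[2], hi[2], hi[2])))
  structure(list(niche = niche, cutoff = cutoff,
                 true_suitability = raster_create(suit, g$xmin, g$ymin,
                                                  g$cellsize),
                 true_range = raster_create(rng, g$xmin, g$ymin, g$cellsize),
                 M_true = M, stack_grid = g),
            class = "virtual_species")
}

#' @export
print.virtual_species <- function(x, ...) {
  cat(sprintf("<virtual_species> niche on %s, cutoff %.2f, range %d cells\n",
              paste(names(x$niche), collapse = ", "), x$cutoff,
              sum(x$true_range$values == 1, na.rm = TRUE)))
  invisible(x)
}

#' Sample an occurrence table from a virtual species
#'
#' Clean records are drawn proportionally to true suitability (optionally
#' times a sampling-bias raster) and jittered within their cell; provenance
#' and documentation fields are populated with varying completeness so the
#' documentation score discriminates records. Corrupted records emulating
#' the error classes experts look for are injected at the stated rates:
#' `zero_coords` (coordinates replaced by (0, 0)), `transposed` (lat/lon
#' swapped), `duplicate` (an exact provenance copy of an earlier record),
#' and `off_range_misID` (a misidentification placed on a
#' low-suitability cell). Ground-truth labels stay out of the record
#' schema: retrieve them with [occurrence_truth()].
#'
#' @param species A `virtual_species`.
#' @param n Number of records (>= 1).
#' @param bias Optional `sdm_raster` of relative sampling effort.
#' @param dem Optional DEM raster; stated elevations are then the DEM value
#'   plus observation noise (sd 50 m), so elevation checks have a truth to
#'   compare against. Without a DEM elevations are uniform draws.
#' @param error_rates Named list of rates in `[0, 1]` summing to <= 1.
#' @param seed Integer seed.
#' @return A raw occurrence data.frame with Darwin-Core-style columns,
#'   carrying a `truth` attribute (character label per row).
#' @export
sample_occurrences <- function(species, n, bias = NULL, dem = NULL,
                               error_rates = list(zero_coords = 0,
                                                  transposed = 0,
                                                  duplicate = 0,
                                                  off_range_misID = 0),
                               seed = 1L) {
  stopifnot(n >= 1)
  rates <- unlist(error_rates)
  stopifnot(all(rates >= 0), all(rates <= 1), sum(rates) <= 1)
  suit <- species$true_suitability$values
  g <- species$stack_grid
  w <- as.vector(suit)
  w[is.na(w)] <- 0
  if (!is.null(bias)) {
    b <- as.vector(bias$values)
    b[is.na(b)] <- 0
    w <- w * b
  }
  if (all(w <= 0)) stop("no sampleable cells (suitability x bias all zero)")
  institutions <- c("MHN", "ICN", "UV", "UDEA", NA)
  withr::with_seed(as.integer(seed), {
    cells <- sample(length(w), n, replace = TRUE, prob = w)
    rc <- arrayInd(cells, dim(suit))
    ctr <- xy_from_cell(species$true_suitability, rc[, 1], rc[, 2])
    lon <- ctr[, 1] + stats::runif(n, -0.5, 0.5) * g$cellsize
    lat <- ctr[, 2] + stats::runif(n, -0.5, 0.5) * g$cellsize
    labels <- sample(c("clean", names(rates)), n, replace = TRUE,
                     prob = c(1 - sum(rates), rates))
    # documentation completeness varies per record
    keep_field <- function(p) stats::runif(n) < p
    df <- data.frame(
      scientificName = "Virtualis exempli",
      decimalLatitude = lat, decimalLongitude = lon,
      institutionCode = sample(institutions, n, replace = TRUE),
      collectionCode = ifelse(keep_field(0.7), "Aves", NA),
      catalogNumber = ifelse(keep_field(0.8),
                             sprintf("cat-%05d", sample(99999, n)), NA),
      occurrenceID = ifelse(keep_field(0.9),
                            sprintf("src-%06d", sample(999999, n)), NA),
      recordedBy = ifelse(keep_field(0.6), "A. Collector", NA),
      eventDate = ifelse(keep_field(0.8),
                         format(as.Date("1990-01-01") +
                                  sample(10000, n, replace = TRUE)), NA),
      locality = ifelse(keep_field(0.5), "synthetic locality", NA),
      elevation = if (is.null(dem)) round(stats::runif(n, 0, 3000)) else
        round(raster_extract(dem, lon, lat) + stats::rnorm(n, 0, 50)),
      stringsAsFactors = FALSE)
    for (i in which(labels == "zero_coords")) {
      df$decimalLatitude[i] <- 0; df$decimalLongitude[i] <- 0
    }
    for (i in which(labels == "transposed")) {
      tmp <- df$decimalLatitude[i]
      df$decimalLatitude[i] <- df$decimalLongitude[i]
      df$decimalLongitude[i] <- tmp
    }
    for (i in which(labels == "duplicate")) {
      src <- if (i > 1) sample(i - 1, 1) else i
      df[i, ] <- df[src, ]
    }
    low <- which(w > 0 & as.vector(suit) < 0.05 & !is.na(as.vector(suit)))
    if (!length(low)) low <- which(!is.na(as.vector(suit)))
    for (i in which(labels == "off_range_misID")) {
      cell <- sample(low, 1)
      rc1 <- arrayInd(cell, dim(suit))
      p <- xy_from_cell(species$true_suitability, rc1[, 1], rc1[, 2])
      df$decimalLatitude[i] <- p[, 2]; df$decimalLongitude[i] <- p[, 1]
    }
  })
  attr(df, "truth") <- labels
  df
}

#' Ground-truth corruption labels of a synthetic occurrence table
#' @param x A table from [sample_occurrences()].
#' @return Character vector: `"clean"` or the injected error class per row.
#' @export
occurrence_truth <- function(x) {
  tr <- attr(x, "truth")
  if (is.null(tr)) stop("table carries no ground-truth labels")
  tr
}

#' Generate a random group progress table
#'
#' Random expert-network progress rows in the shape summarized by
#' [group_summary()] (for the fixed bundled table see
#' [expert_group_table()]).
#'
#' @param seed Integer seed.
#' @param n_groups Number of groups (>= 1).
#' @return Data.frame with the [group_summary()] columns.
#' @export
make_group_table <- function(seed, n_groups) {
  if (n_groups < 1) stop("need at least one group")
  withr::with_seed(as.integer(seed), {
    n_spp <- stats::rnbinom(n_groups, mu = 50, size = 1) + 1
    split <- vapply(n_spp, function(s) {
      stats::rmultinom(1, size = sample(0:s, 1), prob = c(0.6, 0.2, 0.2))
    }, numeric(3))
    data.frame(group = sprintf("group-%02d", seq_len(n_groups)),
               n_experts = stats::rpois(n_groups, 25),
               n_species = n_spp,
               n_under_development = split[1, ],
               n_pending = split[2, ],
               n_validated = split[3, ],
               stringsAsFactors = FALSE)
  })
}
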