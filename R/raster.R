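# Matrix-backed raster grids ------------------------------------------------
#
# A raster is a numeric matrix plus an affine grid: row 1 is the northern-most
# row, column 1 the western-most column, cells are square in degrees and
# half-open ([x, x + cs) along longitude, (y, y + cs] along latitude so the
# top edge belongs to row 1). NA encodes nodata.

#' Create a raster
#'
#' Builds a matrix-backed raster layer on a regular longitude/latitude grid
#' (WGS84 decimal degrees). Row 1 of `values` is the northern-most row of
#' cells and column 1 the western-most; `NA` cells are nodata.
#'
#' @param values Numeric matrix of cell values (rows north to south).
#' @param xmin,ymin Coordinates of the south-west corner of the grid, in
#'   decimal degrees.
#' @param cellsize Cell edge length in decimal degrees (square cells).
#' @param crs Coordinate reference system label; only `"EPSG:4326"` is used.
#' @return An object of class `sdm_raster`.
#' @export
raster_create <- function(values, xmin, ymin, cellsize, crs = "EPSG:4326") {
  stopifnot(is.matrix(values), is.numeric(cellsize), cellsize > 0)
  structure(
    list(values = values, xmin = xmin, ymin = ymin,
         cellsize = cellsize, crs = crs),
    class = "sdm_raster"
  )
}

#' @export
print.sdm_raster <- function(x, ...) {
  cat(sprintf(
    "<sdm_raster> %d x %d cells, cellsize %.6g deg, extent [%.4f, %.4f] x [%.4f, %.4f]\n",
    nrow(x$values), ncol(x$values), x$cellsize,
    x$xmin, raster_xmax(x), x$ymin, raster_ymax(x)))
  v <- x$values[!is.na(x$values)]
  if (length(v)) {
    cat(sprintf("  values: [%.4g, %.4g], %d valid / %d cells\n",
                min(v), max(v), length(v), length(x$values)))
  } else cat("  all nodata\n")
  invisible(x)
}

#' @rdname raster_create
#' @param x An `sdm_raster`.
#' @export
raster_xmax <- function(x) x$xmin + ncol(x$values) * x$cellsize

#' @rdname raster_create
#' @export
raster_ymax <- function(x) x$ymin + nrow(x$values) * x$cellsize

#' Make an empty raster on the grid of another
#' @param template An `sdm_raster` supplying the grid.
#' @param fill Value to fill cells with (default `NA`).
#' @return An `sdm_raster` on the template grid.
#' @export
raster_like <- function(template, fill = NA_real_) {
  raster_create(matrix(fill, nrow(template$values), ncol(template$values)),
                template$xmin, template$ymin, template$cellsize, template$crs)
}

#' @noRd
same_grid <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

#' Cell indices for coordinates
#'
#' Maps points to (row, col) indices on the raster grid; points outside the
#' extent get `NA`. Cells are half-open so a point on a shared edge belongs
#' to exactly one cell.
#'
#' @param x An `sdm_raster`.
#' @param lon,lat Numeric vectors of coordinates.
#' @return A two-column integer matrix (`row`, `col`).
#' @export
cell_from_xy <- function(x, lon, lat) {
  col <- floor((lon - x$xmin) / x$cellsize) + 1L
  row <- floor((raster_ymax(x) - lat) / x$cellsize) + 1L
  # top edge belongs to row 1, left edge to col 1
  row[lat == raster_ymax(x)] <- 1L
  bad <- col < 1L | col > ncol(x$values) | row < 1L | row > nrow(x$values) |
    is.na(lon) | is.na(lat)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Cell-center coordinates
#' @param x An `sdm_raster`.
#' @param row,col Integer vectors of cell indices.
#' @return A two-column matrix (`lon`, `lat`) of cell centers.
#' @export
xy_from_cell <- function(x, row, col) {
  cbind(lon = x$xmin + (col - 0.5) * x$cellsize,
        lat = raster_ymax(x) - (row - 0.5) * x$cellsize)
}

#' Extract raster values at point locations
#' @inheritParams cell_from_xy
#' @return Numeric vector of cell values (`NA` outside the extent or on
#'   nodata cells).
#' @export
raster_extract <- function(x, lon, lat) {
  rc <- cell_from_xy(x, lon, lat)
  out <- rep(NA_real_, length(lon))
  ok <- !is.na(rc[, 1])
  out[ok] <- x$values[cbind(rc[ok, 1], rc[ok, 2])]
  out
}

#' Per-cell area in square kilometres
#'
#' Spherical cell areas; constant along a row, shrinking with `cos(lat)`.
#'
#' @param x An `sdm_raster`.
#' @return A matrix of cell areas (km^2) matching the value matrix.
#' @export
cell_area_km2 <- function(x) {
  km_per_deg <- pi * 6371.0088 / 180
  lat <- raster_ymax(x) - (seq_len(nrow(x$values)) - 0.5) * x$cellsize
  rowarea <- (x$cellsize * km_per_deg)^2 * cos(lat * pi / 180)
  matrix(rowarea, nrow(x$values), ncol(x$values))
}

# ASCII grid I/O -------------------------------------------------------------

#' Read / write rasters as ESRI ASCII grids
#'
#' Plain-text raster exchange format: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' values, northern row first. Text-based, diff-able and portable across GIS
#' tools.
#'
#' @param path File path (`.asc`).
#' @param digits Significant digits written (default 10).
#' @return `read_asc` returns an `sdm_raster`; `write_asc` returns `path`
#'   invisibly.
#' @export
read_asc <- function(path) {
  lines <- readLines(path, n = 6L)
  hdr <- lapply(strsplit(trimws(lines), "\\s+"), function(p) {
    if (length(p) < 2) stop("not an ASCII grid: malformed header")
    list(key = tolower(p[[1]]), val = suppressWarnings(as.numeric(p[[2]])))
  })
  h <- stats::setNames(vapply(hdr, `[[`, 0, "val"),
                       vapply(hdr, `[[`, "", "key"))
  needed <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
              "nodata_value")
  if (!all(needed %in% names(h))) {
    stop("not an ASCII grid: missing header keys in ", path)
  }
  vals <- scan(path, what = numeric(), skip = 6L, quiet = TRUE)
  if (length(vals) != h[["ncols"]] * h[["nrows"]]) {
    stop("ASCII grid value count does not match header in ", path)
  }
  m <- matrix(vals, nrow = h[["nrows"]], ncol = h[["ncols"]], byrow = TRUE)
  m[m == h[["nodata_value"]]] <- NA_real_
  raster_create(m, h[["xllcorner"]], h[["yllcorner"]], h[["cellsize"]])
}

#' @rdname read_asc
#' @param x An `sdm_raster` to write.
#' @param nodata Numeric value standing for `NA` cells in the file.
#' @export
write_asc <- function(x, path, nodata = -9999, digits = 10) {
  m <- x$values
  m[is.na(m)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", x$xmin),
    sprintf("yllcorner %.10g", x$ymin),
    sprintf("cellsize %.10g", x$cellsize),
    sprintf("NODATA_value %.10g", nodata)
  )
  body <- apply(m, 1, function(r) paste(format(r, digits = digits,
                                               trim = TRUE, scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# Environmental stacks -------------------------------------------------------

#' Build a stack of co-registered environmental layers
#'
#' All layers must share the grid exactly (or be resampled onto the first
#' layer's grid with `resample = TRUE`, nearest neighbour). The stack carries
#' a shared validity mask: a cell is valid only where every layer has data,
#' and the mask is pushed back into each layer so nodata is identical across
#' layers.
#'
#' @param layers Named list of `sdm_raster` layers.
#' @param resample Resample mismatched layers onto the first layer's grid
#'   instead of erroring.
#' @return An object of class `env_stack` with elements `layers` (named list
#'   of `sdm_raster`), `grid` (the template raster, nodata-free) and `mask`
#'   (logical matrix of valid cells).
#' @export
env_stack <- function(layers, resample = FALSE) {
  stopifnot(is.list(layers), length(layers) >= 1)
  if (is.null(names(layers)) || anyDuplicated(names(layers)) ||
      any(!nzchar(names(layers)))) {
    stop("layers must be uniquely named")
  }
  template <- layers[[1]]
  layers <- lapply(layers, function(l) {
    if (!identical(l$crs, template$crs)) stop("CRS mismatch across layers")
    if (same_grid(l, template)) return(l)
    if (!resample) stop("layer grids differ; pass resample = TRUE to resample")
    resample_nn(l, template)
  })
  mask <- Reduce(`&`, lapply(layers, function(l) !is.na(l$values)))
  layers <- lapply(layers, function(l) {
    l$values[!mask] <- NA_real_
    l
  })
  structure(list(layers = layers, grid = raster_like(template, 0), mask = mask),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> %d layers (%s), %d x %d cells, %d valid\n",
              length(x$layers), paste(names(x$layers), collapse = ", "),
              nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}

#' @noRd
resample_nn <- function(x, template) {
  ctr <- xy_from_cell(template,
                      row = rep(seq_len(nrow(template$values)),
                                times = ncol(template$values)),
                      col = rep(seq_len(ncol(template$values)),
                                each = nrow(template$values)))
  vals <- raster_extract(x, ctr[, 1], ctr[, 2])
  raster_create(matrix(vals, nrow(template$values), ncol(template$values)),
                template$xmin, template$ymin, template$cellsize, template$crs)
}

#' Load an environmental stack from ASCII grid files
#'
#' @param paths Character vector of `.asc` paths; layer names default to the
#'   file names without extension.
#' @param names Optional layer names.
#' @inheritParams env_stack
#' @return An `env_stack`.
#' @export
load_stack <- function(paths, names = NULL, resample = FALSE) {
  if (is.null(names)) names <- sub("\\.[^.]*$", "", basename(paths))
  layers <- stats::setNames(lapply(paths, read_asc), names)
  env_stack(layers, resample = resample)
}

#' Select a subset of stack layers
#'
#' Environmental-variable selection is an explicit modeling step (experts
#' pick the predictors meaningful for the species); this restricts a stack
#' to the chosen layers, e.g. dropping the DEM and land-cover layers that
#' serve post-processing rather than model fitting.
#'
#' @param stack An `env_stack`.
#' @param names Layer names to keep.
#' @return An `env_stack` with only those layers.
#' @export
stack_subset <- function(stack, names) {
  missing <- setdiff(names, base::names(stack$layers))
  if (length(missing)) stop("no such layer(s): ",
                            paste(missing, collapse = ", "))
  env_stack(stack$layers[names])
}

#' Extract the environmental values of a stack at points
#' @param stack An `env_stack`.
#' @param lon,lat Coordinate vectors.
#' @return A data.frame with one column per layer.
#' @export
stack_extract <- function(stack, lon, lat) {
  as.data.frame(lapply(stack$layers, raster_extract, lon = lon, lat = lat))
}

# Masking --------------------------------------------------------------------

#' Mask a raster by a polygon or by land-cover classes
#'
#' Cells whose centers fall outside `geometry`, or whose land-cover class is
#' not in `classes`, are set to 0 when the raster is binary (all values in
#' \{0, 1\}) and to nodata otherwise. Inside values are unchanged, so masking
#' is idempotent and never adds cells.
#'
#' @param x An `sdm_raster` to mask.
#' @param geometry A `geo_polygon` (see [geo_polygon()]), or `NULL`.
#' @param landcover Categorical `sdm_raster` on the same grid, used with
#'   `classes`.
#' @param classes Vector of allowed land-cover class codes.
#' @return The masked `sdm_raster`.
#' @export
mask_raster <- function(x, geometry = NULL, landcover = NULL, classes = NULL) {
  if (is.null(geometry) && is.null(landcover)) {
    stop("provide a geometry or a landcover raster with allowed classes")
  }
  vals <- x$values
  binary <- all(vals %in% c(0, 1) | is.na(vals))
  outside_val <- if (binary) 0 else NA_real_
  keep <- matrix(TRUE, nrow(vals), ncol(vals))
  if (!is.null(geometry)) {
    keep <- keep & raster_cells_in_polygon(x, geometry)
    if (!any(keep)) warning("geometry is disjoint from the raster extent; all cells masked")
  }
  if (!is.null(landcover)) {
    if (is.null(classes) || length(classes) == 0) {
      stop("allowed land-cover class set is empty")
    }
    if (!same_grid(landcover, x)) stop("landcover raster is not on the template grid")
    keep <- keep & matrix(landcover$values %in% classes, nrow(vals), ncol(vals))
  }
  vals[!keep & !is.na(vals)] <- outside_val
  x$values <- vals
  x
}

#' Rasterize a polygon onto a template grid
#'
#' Cell centers inside the polygon get 1, others 0.
#'
#' @param geometry A `geo_polygon`.
#' @param template An `sdm_raster` supplying the grid.
#' @return A binary `sdm_raster`.
#' @export
rasterize_polygon <- function(geometry, template) {
  inside <- raster_cells_in_polygon(template, geometry)
  raster_create(matrix(as.numeric(inside), nrow(template$values),
                       ncol(template$values)),
                template$xmin, template$ymin, template$cellsize, template$crs)
}

#' @noRd
raster_cells_in_polygon <- function(x, geometry) {
  nr <- nrow(x$values); nc <- ncol(x$values)
  ctr <- xy_from_cell(x, row = rep(seq_len(nr), times = nc),
                      col = rep(seq_len(nc), each = nr))
  matrix(point_in_polygon(geometry, ctr[, 1], ctr[, 2]), nr, nc)
}
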