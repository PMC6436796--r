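# Model registry ---------------------------------------------------------------
#
# Lifecycle: under_development --feedback_processed--> pending_validation
#            pending_validation --approved--> validated (mean score >= 3)
#            validated --reopen--> under_development (new version)
# Externally contributed, peer-reviewed models enter as published_external
# without further review; non-peer-reviewed ones as pending_validation.

#' Create a registry entry for a model
#'
#' @param model_id Unique identifier.
#' @param species Scientific name.
#' @param version Integer version (default 1).
#' @param status Initial status (default `"under_development"`).
#' @param authors Character vector of contributors (data cleaners, input
#'   providers, validators are all recognized as authors).
#' @param metadata Named list: sources, method tag, settings, seeds,
#'   evaluation statistics, modeling-log link, artifact paths.
#' @return A `model_record`.
#' @export
model_record <- function(model_id, species, version = 1L,
                         status = "under_development", authors = character(),
                         metadata = list()) {
  stopifnot(status %in% c("under_development", "pending_validation",
                          "validated", "published_external"))
  structure(list(model_id = model_id, species = species,
                 version = as.integer(version), status = status,
                 scores = data.frame(score = integer(),
                                     reviewer = character(),
                                     stringsAsFactors = FALSE),
                 authors = authors, metadata = metadata,
                 events = list()),
            class = "model_record")
}

#' @export
print.model_record <- function(x, ...) {
  cat(sprintf("<model_record> %s (%s) v%d: %s, %d score(s)\n",
              x$model_id, x$species, x$version, x$status, nrow(x$scores)))
  invisible(x)
}

#' @noRd
lifecycle_edges <- list(
  model_generated = c(from = NA, to = "under_development"),
  feedback_processed = c(from = "under_development",
                         to = "pending_validation"),
  approved = c(from = "pending_validation", to = "validated"),
  external_submission_accepted = c(from = "pending_validation",
                                   to = "published_external"),
  reopen = c(from = "validated", to = "under_development")
)

#' Advance a model through its lifecycle
#'
#' Only the legal edges are taken; anything else errors. `approved`
#' additionally requires a passing score set (see [score_and_decide()]).
#' `reopen` (new distribution hypotheses, taxonomy changes, or substantial
#' new occurrence data) starts a new version. Every transition is logged
#' with a timestamp on the record.
#'
#' @param record A `model_record`.
#' @param event One of `feedback_processed`, `approved`,
#'   `external_submission_accepted`, `reopen`.
#' @param quorum Minimum number of scores required to approve (default 1).
#' @return The updated record.
#' @export
transition <- function(record, event, quorum = 1L) {
  edge <- lifecycle_edges[[event]]
  if (is.null(edge)) stop("unknown lifecycle event: ", event)
  if (is.na(edge[["from"]]) || record$status != edge[["from"]]) {
    stop(sprintf("illegal transition: %s from status %s", event,
                 record$status))
  }
  if (event == "approved") {
    if (nrow(record$scores) < quorum) {
      stop(sprintf("approval requires at least %d score(s)", quorum))
    }
    if (score_and_decide(record$scores$score) != "approved") {
      stop("approval requires a mean expert score of 3 or higher")
    }
  }
  record$status <- edge[["to"]]
  if (event == "reopen") {
    record$version <- record$version + 1L
    record$scores <- record$scores[0, ]
  }
  record$events <- c(record$events,
                     list(list(event = event, to = record$status,
                               timestamp = format(Sys.time(),
                                                  "%Y-%m-%dT%H:%M:%SZ",
                                                  tz = "UTC"))))
  record
}

#' Add expert credibility scores to a model
#'
#' Scores are on a qualitative 1-5 scale (1: no credibility, 5: complete
#' credibility), one per reviewer.
#'
#' @param record A `model_record`.
#' @param scores Integer vector in 1..5.
#' @param reviewers Reviewer identifiers (recycled if length 1).
#' @return The updated record.
#' @export
add_scores <- function(record, scores, reviewers = "anonymous") {
  check_scores(scores)
  reviewers <- rep_len(reviewers, length(scores))
  record$scores <- rbind(record$scores,
                         data.frame(score = as.integer(scores),
                                    reviewer = reviewers,
                                    stringsAsFactors = FALSE))
  record
}

#' @noRd
check_scores <- function(scores) {
  if (!length(scores) || any(is.na(scores)) ||
      any(scores != as.integer(scores)) || any(scores < 1 | scores > 5)) {
    stop("scores must be integers in 1..5")
  }
}

#' The validation decision rule
#'
#' A model is approved when the arithmetic mean of its expert scores is 3 or
#' higher; otherwise it stays pending and experts may revise their inputs or
#' request a new model.
#'
#' @param scores Integer vector of 1-5 scores.
#' @return `"approved"` or `"pending"`.
#' @export
score_and_decide <- function(scores) {
  check_scores(scores)
  if (mean(scores) >= 3) "approved" else "pending"
}

#' Register an externally contributed model
#'
#' Third-party models enter the registry with their raster, metadata and
#' optional occurrences. Submissions backed by peer-reviewed research are
#' published immediately; others await a methods review. Mandatory metadata
#' fields must be present.
#'
#' @param model_id,species Identifiers.
#' @param metadata Named list; must contain the `required_fields`.
#' @param peer_reviewed Was the model used in peer-reviewed research?
#' @param required_fields Mandatory metadata keys.
#' @return A `model_record` with the appropriate status.
#' @export
intake_external <- function(model_id, species, metadata,
                            peer_reviewed = FALSE,
                            required_fields = c("sources", "method",
                                                "methods_document")) {
  missing <- setdiff(required_fields,
                     names(metadata)[!vapply(metadata, is.null, FALSE)])
  if (length(missing)) {
    stop("submission rejected; missing metadata field(s): ",
         paste(missing, collapse = ", "))
  }
  status <- if (peer_reviewed) "published_external" else "pending_validation"
  rec <- model_record(model_id, species, status = status,
                      metadata = metadata)
  rec$events <- list(list(event = "intake_external",
                          to = status,
                          timestamp = format(Sys.time(),
                                             "%Y-%m-%dT%H:%M:%SZ",
                                             tz = "UTC")))
  rec
}

# Fact-sheet statistics --------------------------------------------------------

#' Distribution statistics for a binary range map
#'
#' The range summaries used to assess conservation status (IUCN criteria
#' B1/B2): model area (sum of presence-cell areas, km^2), extent of
#' occurrence (geodesic area of the convex hull of presence-cell centers;
#' degenerates to the summed cell area below 3 distinct cells), area of
#' occupancy (occupied 2 x 2-km cells x 4 km^2), and the elevation range
#' over presence cells when a DEM is given.
#'
#' @param binary A binary `sdm_raster`.
#' @param dem Optional DEM `sdm_raster` on the same grid.
#' @return List: `area_km2`, `eoo_km2`, `aoo_km2`, `elevation_range`
#'   (`c(min, max)` or `NULL`), `n_cells`.
#' @export
distribution_stats <- function(binary, dem = NULL) {
  pres <- which(binary$values == 1)
  if (!length(pres)) {
    warning("empty distribution; all statistics are zero")
    return(list(area_km2 = 0, eoo_km2 = 0, aoo_km2 = 0,
                elevation_range = NULL, n_cells = 0L))
  }
  area <- sum(cell_area_km2(binary)[pres])
  rc <- arrayInd(pres, dim(binary$values))
  ctr <- xy_from_cell(binary, rc[, 1], rc[, 2])
  eoo <- if (nrow(unique(ctr)) < 3) area else {
    hull <- tryCatch(convex_hull(ctr[, 1], ctr[, 2]), error = function(e) NULL)
    if (is.null(hull)) area else
      max(polygon_area_km2(hull), area)
  }
  # AOO on a 2-km lattice (1/60 degree), anchored at the raster origin
  cs2 <- 1 / 60
  occ2 <- unique(cbind(floor((ctr[, 1] - binary$xmin) / cs2),
                       floor((ctr[, 2] - binary$ymin) / cs2)))
  aoo <- nrow(occ2) * 4
  elev <- NULL
  if (!is.null(dem)) {
    if (!same_grid(dem, binary)) stop("DEM is not on the template grid")
    ev <- dem$values[pres]
    if (any(!is.na(ev))) elev <- range(ev, na.rm = TRUE)
  }
  list(area_km2 = area, eoo_km2 = eoo, aoo_km2 = aoo,
       elevation_range = elev, n_cells = length(pres))
}

# Group progress tables --------------------------------------------------------

#' Column totals of a group progress table
#'
#' Summarizes an expert-network progress table (one row per expert group
#' with expert, species and per-status model counts; blank cells read as
#' zero) into its totals row.
#'
#' @param table Data.frame with columns `group`, `n_experts`, `n_species`,
#'   `n_under_development`, `n_pending`, `n_validated`.
#' @return Named numeric vector of column totals.
#' @export
group_summary <- function(table) {
  cols <- c("n_experts", "n_species", "n_under_development", "n_pending",
            "n_validated")
  stopifnot(all(cols %in% names(table)))
  vapply(table[cols], function(col) {
    col <- suppressWarnings(as.numeric(col))
    col[is.na(col)] <- 0
    if (any(col < 0)) stop("negative count in group table")
    sum(col)
  }, 0)
}

#' Read a group progress table from CSV
#' @param path CSV with the [group_summary()] columns.
#' @return Data.frame.
#' @export
read_group_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' The bundled expert-network progress table
#'
#' The 18-group progress table shipped with the package (counts of experts,
#' species, and models per development status for each expert group of a
#' national implementation; blanks are zeros).
#'
#' @return Data.frame of 18 rows.
#' @export
expert_group_table <- function() {
  read_group_table(system.file("extdata", "expert_group_table.csv",
                               package = "sdmflow", mustWork = TRUE))
}

# Registry persistence ---------------------------------------------------------

#' Write / read a model record as JSON
#'
#' Lossless round trip of the registry document (status, scores, authors,
#' metadata, event log).
#'
#' @param record A `model_record`.
#' @param path JSON path.
#' @return `write_model_record`: `path` invisibly; `read_model_record`: the
#'   record.
#' @export
write_model_record <- function(record, path) {
  doc <- unclass(record)
  doc$scores <- as.list(doc$scores)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model_record
#' @export
read_model_record <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  rec <- model_record(doc$model_id, doc$species, version = doc$version,
                      status = doc$status,
                      authors = unlist(doc$authors) %||% character(),
                      metadata = doc$metadata)
  rec$scores <- data.frame(score = as.integer(unlist(doc$scores$score)),
                           reviewer = as.character(unlist(doc$scores$reviewer)),
                           stringsAsFactors = FALSE)
  rec$events <- doc$events
  rec
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
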