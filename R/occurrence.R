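# Occurrence curation --------------------------------------------------------
#
# Records live in a plain data.frame inside an `occ_dataset` together with an
# append-only audit log and the curation configuration. Flags are stored as
# "|"-joined code strings so the whole state is flat, diff-able and CSV-safe.

#' @noRd
occ_columns <- c("uid", "taxon", "lat", "lon", "elevation_m", "event_date",
                 "locality", "institution", "collection_code",
                 "catalog_number", "recorded_by", "source_occurrence_id",
                 "doc_score", "auto_flags", "manual_flags", "visible")

#' Darwin-Core-style column mapping
#'
#' Maps the occurrence CSV headers used for exchange onto the internal
#' record fields. Override entries to ingest differently-named tables.
#'
#' @return Named character vector: names are source columns, values internal
#'   fields.
#' @export
dwc_field_map <- function() {
  c(scientificName = "taxon", decimalLatitude = "lat",
    decimalLongitude = "lon", elevation = "elevation_m",
    eventDate = "event_date", locality = "locality",
    institutionCode = "institution", collectionCode = "collection_code",
    catalogNumber = "catalog_number", recordedBy = "recorded_by",
    occurrenceID = "source_occurrence_id")
}

#' @noRd
default_doc_fields <- function() {
  c("event_date", "elevation_m", "locality", "institution",
    "collection_code", "catalog_number", "recorded_by",
    "source_occurrence_id")
}

#' Default automated flag rules
#'
#' Each rule is a pure predicate of the record table and optional reference
#' layers. The default set covers the common coordinate and provenance error
#' classes: missing or (0, 0) coordinates, points outside the study region,
#' latitude/longitude transposition candidates (the swapped point falls
#' inside the region while the original does not), elevation disagreeing
#' with a DEM by more than `elev_tol_m`, exact provenance duplicates, and
#' event dates in the future.
#'
#' @param elev_tol_m Elevation tolerance against the DEM, metres.
#' @param reference_date Date records are compared against for FUTURE_DATE.
#' @return Named list of flag rules (code, kind, requires, predicate).
#' @export
default_flag_rules <- function(elev_tol_m = 500,
                               reference_date = Sys.Date()) {
  rule <- function(code, requires, predicate) {
    list(code = code, kind = "automated", requires = requires,
         predicate = predicate)
  }
  list(
    MISSING_COORDS = rule("MISSING_COORDS", character(), function(rec, ref) {
      is.na(rec$lat) | is.na(rec$lon)
    }),
    ZERO_COORDS = rule("ZERO_COORDS", character(), function(rec, ref) {
      !is.na(rec$lat) & !is.na(rec$lon) & rec$lat == 0 & rec$lon == 0
    }),
    OUT_OF_REGION = rule("OUT_OF_REGION", "region", function(rec, ref) {
      ok <- !is.na(rec$lat) & !is.na(rec$lon)
      out <- rep(FALSE, nrow(rec))
      out[ok] <- !point_in_polygon(ref$region, rec$lon[ok], rec$lat[ok])
      out
    }),
    COORD_SWAP = rule("COORD_SWAP", "region", function(rec, ref) {
      ok <- !is.na(rec$lat) & !is.na(rec$lon)
      out <- rep(FALSE, nrow(rec))
      out[ok] <- !point_in_polygon(ref$region, rec$lon[ok], rec$lat[ok]) &
        point_in_polygon(ref$region, rec$lat[ok], rec$lon[ok])
      out
    }),
    ELEV_MISMATCH = rule("ELEV_MISMATCH", "dem", function(rec, ref) {
      ok <- !is.na(rec$lat) & !is.na(rec$lon) & !is.na(rec$elevation_m)
      out <- rep(FALSE, nrow(rec))
      dem <- raster_extract(ref$dem, rec$lon[ok], rec$lat[ok])
      out[ok] <- !is.na(dem) & abs(rec$elevation_m[ok] - dem) > elev_tol_m
      out
    }),
    DUPLICATE_EXACT = rule("DUPLICATE_EXACT", character(), function(rec, ref) {
      key <- paste(rec$source_occurrence_id, rec$institution,
                   rec$collection_code, rec$catalog_number, sep = "\r")
      has_prov <- !(is.na(rec$source_occurrence_id) & is.na(rec$institution) &
                      is.na(rec$collection_code) & is.na(rec$catalog_number))
      duplicated(key) & has_prov
    }),
    FUTURE_DATE = rule("FUTURE_DATE", character(), function(rec, ref) {
      d <- suppressWarnings(as.Date(rec$event_date))
      !is.na(d) & d > reference_date
    })
  )
}

#' @noRd
manual_flag_codes <- function() c("SUSPECT_ID", "GEOREF_ERROR", "OTHER")

#' Default blocking flag set
#'
#' Flags that hide a record from modeling under the default visibility
#' filter. Per-dataset filters swap this set out.
#'
#' @return Character vector of flag codes.
#' @export
default_blocking_flags <- function() {
  c("MISSING_COORDS", "ZERO_COORDS", "OUT_OF_REGION", "COORD_SWAP",
    "DUPLICATE_EXACT", "SPATIAL_DUPLICATE", "SUSPECT_ID", "GEOREF_ERROR")
}

# flag-string helpers: flags are "|"-joined sorted code strings
#' @noRd
flags_to_string <- function(codes) {
  paste(sort(unique(codes)), collapse = "|")
}

#' @noRd
flags_from_string <- function(s) {
  if (is.na(s) || !nzchar(s)) character() else strsplit(s, "|", fixed = TRUE)[[1]]
}

#' @noRd
has_flag <- function(flag_str, code) {
  vapply(flag_str, function(s) code %in% flags_from_string(s), FALSE,
         USE.NAMES = FALSE)
}

#' Standardize a raw occurrence table
#'
#' Turns an aggregated occurrence table into a curated dataset: every row
#' gets a fresh permanent identifier, provenance columns are preserved
#' verbatim, the documentation score is computed, and coordinate columns are
#' coerced to numeric (unparseable coordinates flag the record
#' MISSING_COORDS rather than dropping it).
#'
#' @param raw A data.frame of occurrences.
#' @param field_map Named character vector mapping raw columns to internal
#'   fields; see [dwc_field_map()].
#' @param uid_prefix Prefix for generated permanent identifiers.
#' @param flag_rules Automated rule set, see [default_flag_rules()].
#' @param blocking Blocking flag codes, see [default_blocking_flags()].
#' @param doc_fields Fields counted by the documentation score.
#' @return An `occ_dataset`: list with `records` (data.frame), `audit`
#'   (append-only log) and `config`.
#' @export
occ_standardize <- function(raw, field_map = dwc_field_map(),
                            uid_prefix = "occ",
                            flag_rules = default_flag_rules(),
                            blocking = default_blocking_flags(),
                            doc_fields = default_doc_fields()) {
  stopifnot(is.data.frame(raw))
  mandatory <- c("taxon", "lat", "lon")
  present <- field_map[names(field_map) %in% names(raw)]
  if (!all(mandatory %in% present)) {
    stop("configuration error: raw table has no mappable column for: ",
         paste(setdiff(mandatory, present), collapse = ", "))
  }
  n <- nrow(raw)
  rec <- data.frame(uid = sprintf("%s-%06d", uid_prefix, seq_len(n)),
                    stringsAsFactors = FALSE)
  for (f in setdiff(occ_columns, c("uid", "doc_score", "auto_flags",
                                   "manual_flags", "visible"))) {
    src <- names(present)[match(f, present)]
    col <- if (!is.na(src)) raw[[src]] else rep(NA, n)
    if (f %in% c("lat", "lon", "elevation_m")) {
      col <- suppressWarnings(as.numeric(col))
    } else {
      col <- as.character(col)
      col[!is.na(col) & !nzchar(col)] <- NA_character_
    }
    rec[[f]] <- col
  }
  rec$doc_score <- compute_doc_score(rec, doc_fields)
  rec$auto_flags <- ifelse(is.na(rec$lat) | is.na(rec$lon),
                           "MISSING_COORDS", "")
  rec$manual_flags <- ""
  rec$visible <- TRUE
  ds <- structure(
    list(records = rec,
         audit = empty_audit(),
         config = list(field_map = field_map, doc_fields = doc_fields,
                       flag_rules = flag_rules, blocking = blocking)),
    class = "occ_dataset")
  apply_visibility_filter(ds)
}

#' @export
print.occ_dataset <- function(x, ...) {
  cat(sprintf("<occ_dataset> %d records (%d visible), %d audit entries\n",
              nrow(x$records), sum(x$records$visible), nrow(x$audit)))
  invisible(x)
}

#' @noRd
compute_doc_score <- function(rec, doc_fields) {
  as.integer(rowSums(!is.na(as.matrix(rec[doc_fields]))))
}

#' Run the automated quality checks
#'
#' Evaluates every automated flag rule whose reference layers are available;
#' each record's automated flags become exactly the set of rule codes whose
#' predicate holds (the dedup flag SPATIAL_DUPLICATE, managed by
#' [occ_dedupe()], is preserved). Re-running changes nothing.
#'
#' @param ds An `occ_dataset`.
#' @param reference Named list of reference layers: `region` (a
#'   `geo_polygon`), `dem` (an `sdm_raster`), as required by the rules.
#' @return The dataset with `auto_flags` populated and visibility refreshed.
#' @export
occ_run_checks <- function(ds, reference = list()) {
  rules <- ds$config$flag_rules
  rec <- ds$records
  hits <- lapply(rules, function(rl) {
    missing_ref <- setdiff(rl$requires, names(reference))
    if (length(missing_ref)) {
      warning(sprintf("rule %s skipped: missing reference layer(s) %s",
                      rl$code, paste(missing_ref, collapse = ", ")),
              call. = FALSE)
      return(NULL)
    }
    which(rl$predicate(rec, reference))
  })
  keep_dup <- has_flag(rec$auto_flags, "SPATIAL_DUPLICATE")
  new_flags <- character(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    codes <- names(rules)[vapply(hits, function(h) !is.null(h) && i %in% h,
                                 FALSE)]
    if (keep_dup[i]) codes <- c(codes, "SPATIAL_DUPLICATE")
    new_flags[i] <- flags_to_string(codes)
  }
  ds$records$auto_flags <- new_flags
  apply_visibility_filter(ds)
}

#' Apply the visibility filter
#'
#' A record is visible exactly when none of its flags (automated or manual,
#' including the dedup flag) is in the blocking set. The blocking set is
#' per-dataset configuration, so groups with sparse data can run laxer
#' filters.
#'
#' @param ds An `occ_dataset`.
#' @param blocking Blocking flag codes; defaults to the dataset's
#'   configuration.
#' @return The dataset with `visible` recomputed.
#' @export
apply_visibility_filter <- function(ds, blocking = NULL) {
  if (is.null(blocking)) blocking <- ds$config$blocking
  known <- c(names(ds$config$flag_rules), manual_flag_codes(),
             "SPATIAL_DUPLICATE", "MISSING_COORDS")
  unknown <- setdiff(blocking, known)
  if (length(unknown)) {
    stop("configuration error: unknown flag code(s) in blocking set: ",
         paste(unknown, collapse = ", "))
  }
  ds$config$blocking <- blocking
  rec <- ds$records
  ds$records$visible <- vapply(seq_len(nrow(rec)), function(i) {
    codes <- c(flags_from_string(rec$auto_flags[i]),
               flags_from_string(rec$manual_flags[i]))
    !any(codes %in% blocking)
  }, FALSE)
  ds
}

#' Spatial deduplication on a 1-km grid
#'
#' When several visibility-eligible records fall in the same grid cell
#' (default: a 30-arc-second lattice anchored at the floor of the dataset's
#' bounding-box origin, roughly 1 km at the equator), only the most
#' documented record stays visible; the others are flagged
#' SPATIAL_DUPLICATE. Ties on the documentation score go to the earliest
#' permanent identifier, for determinism. Records with invalid coordinates
#' are untouched, and the flag is recomputed from scratch on every call.
#'
#' @param ds An `occ_dataset`.
#' @param cellsize_deg Grid cell size in degrees (default 1/120, i.e. 30
#'   arc-seconds).
#' @param origin Optional `c(lon, lat)` grid anchor; defaults to the floored
#'   bounding-box minimum.
#' @return The dataset with dedup flags and visibility refreshed.
#' @export
occ_dedupe <- function(ds, cellsize_deg = 1 / 120, origin = NULL) {
  rec <- ds$records
  # recompute from scratch: drop stale dedup flags
  rec$auto_flags <- vapply(rec$auto_flags, function(s) {
    flags_to_string(setdiff(flags_from_string(s), "SPATIAL_DUPLICATE"))
  }, "", USE.NAMES = FALSE)
  ds$records <- rec
  ds <- apply_visibility_filter(ds)
  rec <- ds$records
  ok <- !is.na(rec$lat) & !is.na(rec$lon)
  eligible <- ok & ds$records$visible
  if (any(eligible)) {
    if (is.null(origin)) {
      origin <- c(floor(min(rec$lon[ok])), floor(min(rec$lat[ok])))
    }
    cell <- paste(floor((rec$lon - origin[1]) / cellsize_deg),
                  floor((rec$lat - origin[2]) / cellsize_deg))
    for (cl in unique(cell[eligible])) {
      idx <- which(eligible & cell == cl)
      if (length(idx) < 2) next
      winner <- idx[order(-rec$doc_score[idx], rec$uid[idx])][1]
      for (i in setdiff(idx, winner)) {
        rec$auto_flags[i] <- flags_to_string(
          c(flags_from_string(rec$auto_flags[i]), "SPATIAL_DUPLICATE"))
      }
    }
    ds$records <- rec
  }
  apply_visibility_filter(ds)
}

# Audited edits ---------------------------------------------------------------

#' @noRd
empty_audit <- function() {
  data.frame(entry_id = integer(), uid = character(), field = character(),
             old_value = character(), new_value = character(),
             actor = character(), timestamp = character(),
             stringsAsFactors = FALSE)
}

#' @noRd
serialize_value <- function(v) {
  as.character(jsonlite::toJSON(v, auto_unbox = TRUE, digits = NA,
                                null = "null", na = "null"))
}

#' @noRd
deserialize_value <- function(s) jsonlite::fromJSON(s)

#' @noRd
editable_fields <- c("lat", "lon", "taxon", "manual_flags")

#' Edit a record, with audit logging
#'
#' Applies an expert correction to an editable field (coordinates, taxon or
#' manual flags) and appends one entry to the append-only audit log.
#' Permanent identifiers and provenance fields are immutable. Visibility is
#' recomputed; automated flags are re-evaluated when `reference` layers are
#' supplied and a coordinate changed.
#'
#' @param ds An `occ_dataset`.
#' @param uid Permanent identifier of the record.
#' @param field One of `lat`, `lon`, `taxon`, `manual_flags`. Manual flags
#'   are passed as a character vector of codes (or a single "|"-joined
#'   string).
#' @param new_value The corrected value.
#' @param actor Curator identifier for the log.
#' @param reference Optional reference layers for re-running automated
#'   checks after a coordinate edit.
#' @return The updated dataset.
#' @export
occ_edit <- function(ds, uid, field, new_value, actor, reference = NULL) {
  i <- match(uid, ds$records$uid)
  if (is.na(i)) stop("unknown uid: ", uid)
  if (!field %in% editable_fields) {
    stop("field not editable (immutable identifier/provenance): ", field)
  }
  if (field %in% c("lat", "lon")) new_value <- as.numeric(new_value)
  if (field == "manual_flags") {
    bad <- setdiff(flags_from_string(flags_to_string(new_value)),
                   manual_flag_codes())
    if (length(bad)) stop("unknown manual flag code(s): ",
                          paste(bad, collapse = ", "))
    new_value <- flags_to_string(new_value)
  }
  old_value <- ds$records[[field]][i]
  entry <- data.frame(
    entry_id = if (nrow(ds$audit)) max(ds$audit$entry_id) + 1L else 1L,
    uid = uid, field = field,
    old_value = serialize_value(old_value),
    new_value = serialize_value(new_value),
    actor = actor,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC"),
    stringsAsFactors = FALSE)
  ds$audit <- rbind(ds$audit, entry)
  ds$records[[field]][i] <- new_value
  ds$records$doc_score <- compute_doc_score(ds$records, ds$config$doc_fields)
  if (!is.null(reference) && field %in% c("lat", "lon")) {
    ds <- occ_run_checks(ds, reference)
  }
  apply_visibility_filter(ds)
}

#' Revert a record to an earlier state
#'
#' Replays the audit entries of a record newest-first, restoring each
#' field's logged old value, back to (and including) `to_entry_id`. The log
#' stays append-only: each reversal is itself logged as a compensating
#' entry. With `to_entry_id = NULL` all edits of the record are undone; a
#' record with no edits is returned unchanged.
#'
#' @param ds An `occ_dataset`.
#' @param uid Permanent identifier.
#' @param to_entry_id Revert this entry and everything after it (for this
#'   record). `NULL` reverts all.
#' @param actor Curator identifier logged for the compensating entries.
#' @return The updated dataset.
#' @export
occ_revert <- function(ds, uid, to_entry_id = NULL, actor = "revert") {
  i <- match(uid, ds$records$uid)
  if (is.na(i)) stop("unknown uid: ", uid)
  mine <- ds$audit[ds$audit$uid == uid, , drop = FALSE]
  if (!is.null(to_entry_id)) {
    if (!to_entry_id %in% mine$entry_id) {
      stop("entry ", to_entry_id, " not found for record ", uid)
    }
    mine <- mine[mine$entry_id >= to_entry_id, , drop = FALSE]
  }
  if (!nrow(mine)) return(ds)  # untouched record: no-op
  for (k in rev(seq_len(nrow(mine)))) {
    old <- deserialize_value(mine$old_value[k])
    if (is.null(old)) old <- NA
    ds <- occ_edit(ds, uid, mine$field[k], old, actor = actor)
  }
  ds
}

# I/O -------------------------------------------------------------------------

#' Write / read curated occurrences as CSV
#'
#' Darwin-Core-style headers plus the curation columns (uid, docScore,
#' autoFlags, manualFlags, visible). Coordinates are written with 17
#' significant digits so the write/read round trip reproduces every field
#' exactly.
#'
#' @param ds An `occ_dataset` (or its record data.frame).
#' @param path Output CSV path.
#' @return `write_occurrences`: `path` invisibly; `read_occurrences`: an
#'   `occ_dataset`.
#' @export
write_occurrences <- function(ds, path) {
  rec <- if (inherits(ds, "occ_dataset")) ds$records else ds
  out <- data.frame(uid = rec$uid, stringsAsFactors = FALSE)
  inv <- stats::setNames(names(dwc_field_map()), dwc_field_map())
  for (f in setdiff(occ_columns, "uid")) {
    header <- switch(f, doc_score = "docScore", auto_flags = "autoFlags",
                     manual_flags = "manualFlags", visible = "visible",
                     inv[[f]])
    col <- rec[[f]]
    if (is.numeric(col)) col <- formatC(col, digits = 17, format = "g")
    col[is.na(rec[[f]])] <- ""
    out[[header]] <- col
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_occurrences
#' @inheritParams occ_standardize
#' @export
read_occurrences <- function(path, flag_rules = default_flag_rules(),
                             blocking = default_blocking_flags(),
                             doc_fields = default_doc_fields()) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  rec <- data.frame(uid = raw$uid, stringsAsFactors = FALSE)
  fmap <- dwc_field_map()
  for (f in setdiff(occ_columns, c("uid", "doc_score", "auto_flags",
                                   "manual_flags", "visible"))) {
    col <- raw[[names(fmap)[match(f, fmap)]]]
    col[!nzchar(col)] <- NA
    rec[[f]] <- if (f %in% c("lat", "lon", "elevation_m")) as.numeric(col)
    else col
  }
  rec$doc_score <- as.integer(raw$docScore)
  rec$auto_flags <- ifelse(is.na(raw$autoFlags), "", raw$autoFlags)
  rec$manual_flags <- ifelse(is.na(raw$manualFlags), "", raw$manualFlags)
  rec$visible <- raw$visible == "TRUE"
  structure(list(records = rec, audit = empty_audit(),
                 config = list(field_map = fmap, doc_fields = doc_fields,
                               flag_rules = flag_rules, blocking = blocking)),
            class = "occ_dataset")
}

#' Write / read the audit log as JSON Lines
#'
#' One JSON object per line, in entry order.
#'
#' @param ds An `occ_dataset` (or an audit data.frame).
#' @param path Output path.
#' @return `write_audit_log`: `path` invisibly; `read_audit_log`: the audit
#'   data.frame.
#' @export
write_audit_log <- function(ds, path) {
  audit <- if (inherits(ds, "occ_dataset")) ds$audit else ds
  lines <- vapply(seq_len(nrow(audit)), function(i) {
    as.character(jsonlite::toJSON(as.list(audit[i, ]), auto_unbox = TRUE,
                                  digits = NA))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_audit_log
#' @export
read_audit_log <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) return(empty_audit())
  rows <- lapply(lines, function(l) {
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$entry_id <- as.integer(out$entry_id)
  out
}
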