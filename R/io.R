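# Readers and writers for the package's table and geometry formats.
# Tables are plain CSV (UTF-8, header row, "." decimal separator);
# polygons are GeoJSON FeatureCollections (exterior ring only) or WKT
# POLYGON strings in a two-column CSV. Coordinates are planar equal-area
# units; no CRS handling happens here.

PAIR_COLUMNS <- c("pair_id", "species_a", "species_b", "branch_length_my")

#' Read a sister-pair table
#'
#' Reads and validates the standard pair CSV. Required columns: `pair_id`,
#' `species_a`, `species_b`, `branch_length_my`; optional: `overlap_index`
#' (may be blank when polygons are supplied separately) and `category`
#' (always re-derived from the index). Rows violating an invariant are
#' reported with their line numbers.
#'
#' @param path Path to a CSV file.
#' @return A tibble of validated pair records, with `category` derived
#'   where `overlap_index` is present.
#' @export
read_pair_table <- function(path) {
  tab <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) stop("cannot read '", path, "': ", conditionMessage(e),
      call. = FALSE
    )
  )
  if (nrow(tab) == 0 && ncol(tab) == 0) {
    stop("schema error: '", path, "' is empty", call. = FALSE)
  }
  missing <- setdiff(PAIR_COLUMNS, names(tab))
  if (length(missing) > 0) {
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (!"overlap_index" %in% names(tab)) tab$overlap_index <- NA_real_
  tab$branch_length_my <- as.numeric(tab$branch_length_my)
  tab$overlap_index <- as.numeric(tab$overlap_index)

  # data line numbers: header is line 1
  line <- seq_len(nrow(tab)) + 1L
  bad_bl <- is.na(tab$branch_length_my) | tab$branch_length_my <= 0
  if (any(bad_bl)) {
    stop(
      "row error: branch_length_my must be positive (line",
      if (sum(bad_bl) > 1) "s " else " ",
      paste(line[bad_bl], collapse = ", "), ")",
      call. = FALSE
    )
  }
  bad_ov <- !is.na(tab$overlap_index) &
    (tab$overlap_index < 0 | tab$overlap_index > 1)
  if (any(bad_ov)) {
    stop(
      "row error: overlap_index must lie in [0, 1] (line",
      if (sum(bad_ov) > 1) "s " else " ",
      paste(line[bad_ov], collapse = ", "), ")",
      call. = FALSE
    )
  }
  if (anyDuplicated(tab$pair_id)) {
    stop("row error: duplicate pair_id ",
      paste(unique(tab$pair_id[duplicated(tab$pair_id)]), collapse = ", "),
      call. = FALSE
    )
  }
  tab$category <- NA_character_
  has_ov <- !is.na(tab$overlap_index)
  tab$category[has_ov] <-
    as.character(classify_overlap(tab$overlap_index[has_ov]))
  tibble::as_tibble(tab)
}

#' Write a sister-pair table
#'
#' @param pairs A pair table (see [read_pair_table()] for the schema).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(pairs, path) {
  missing <- setdiff(PAIR_COLUMNS, names(pairs))
  if (length(missing) > 0) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  readr::write_csv(tibble::as_tibble(pairs), path, progress = FALSE)
  invisible(path)
}

#' Read species range polygons
#'
#' Accepts either a GeoJSON FeatureCollection of Polygon features (exterior
#' ring only; each feature needs a `species_id` property) or a CSV with
#' columns `species_id` and `wkt` holding `POLYGON ((...))` strings. The
#' format is chosen by file extension (`.json` / `.geojson` vs anything
#' else) unless `format` is given.
#'
#' @param path Input file path.
#' @param format `"geojson"`, `"wkt"`, or `"auto"`.
#' @return A named list of [range_polygon()] objects keyed by species id.
#' @export
read_polygons <- function(path, format = c("auto", "geojson", "wkt")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(geo)?json$", path, ignore.case = TRUE)) {
      "geojson"
    } else {
      "wkt"
    }
  }
  polys <- if (format == "geojson") {
    read_polygons_geojson(path)
  } else {
    read_polygons_wkt(path)
  }
  ids <- vapply(polys, function(p) p$species_id, character(1))
  if (anyNA(ids) || any(ids == "")) {
    stop("schema error: every polygon needs a species_id", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate species_id: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", "),
      call. = FALSE
    )
  }
  stats::setNames(polys, ids)
}

read_polygons_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("schema error: expected a GeoJSON FeatureCollection", call. = FALSE)
  }
  purrr::map(gj$features, function(f) {
    sid <- f$properties$species_id
    if (is.null(sid)) {
      stop("schema error: feature without a species_id property",
        call. = FALSE
      )
    }
    if (is.null(f$geometry$type) || f$geometry$type != "Polygon") {
      stop("schema error: non-Polygon geometry for species '", sid, "'",
        call. = FALSE
      )
    }
    ring <- f$geometry$coordinates[[1]] # exterior ring only
    x <- vapply(ring, function(pt) as.numeric(pt[[1]]), numeric(1))
    y <- vapply(ring, function(pt) as.numeric(pt[[2]]), numeric(1))
    range_polygon(x, y, species_id = sid)
  })
}

read_polygons_wkt <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("species_id", "wkt") %in% names(tab))) {
    stop("schema error: WKT input needs columns species_id, wkt",
      call. = FALSE
    )
  }
  purrr::map2(tab$species_id, tab$wkt, function(sid, w) {
    m <- regmatches(w, regexec(
      "^\\s*POLYGON\\s*\\(\\(\\s*(.*?)\\s*\\)\\)", w,
      ignore.case = TRUE
    ))[[1]]
    if (length(m) < 2) {
      stop("schema error: cannot parse WKT for species '", sid, "'",
        call. = FALSE
      )
    }
    coords <- strsplit(strsplit(m[2], "\\s*,\\s*")[[1]], "\\s+")
    x <- vapply(coords, function(p) as.numeric(p[1]), numeric(1))
    y <- vapply(coords, function(p) as.numeric(p[2]), numeric(1))
    if (anyNA(x) || anyNA(y)) {
      stop("schema error: non-numeric WKT coordinate for species '", sid,
        "'",
        call. = FALSE
      )
    }
    range_polygon(x, y, species_id = sid)
  })
}

#' Write species range polygons as GeoJSON
#'
#' @param polygons Named list of [range_polygon()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_polygons <- function(polygons, path) {
  features <- purrr::imap(polygons, function(p, sid) {
    ring <- purrr::map2(
      c(p$x, p$x[1]), c(p$y, p$y[1]), function(xx, yy) c(xx, yy)
    )
    list(
      type = "Feature",
      properties = list(species_id = sid),
      geometry = list(type = "Polygon", coordinates = list(ring))
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = unname(features)),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write a simulation sweep result
#'
#' @param sweep A [run_sweep()] tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  readr::write_csv(tibble::as_tibble(sweep), path, progress = FALSE)
  invisible(path)
}

#' Read a simulation sweep result
#'
#' @param path CSV written by [write_sweep()].
#' @return A `sweep_result` tibble.
#' @export
read_sweep <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c(
    "movement_sd", "movement_mean", "ancestral_fraction", "geometry",
    "n_sympatric", "replicate", "n", "z", "c", "bimodality"
  )
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  class(tab) <- c("sweep_result", class(tab))
  tab
}
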