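# CSV readers/writers for the documented table schemas, ground-truth JSON,
# and the flat key:value configuration file.

# schema: named character vector column -> "character"/"numeric"/"integer"
read_table_checked <- function(path, schema, what) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "ciliadyn_io_error")
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE)
  missing <- setdiff(names(schema), names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s file %s is missing required column(s): %s",
      what, path, paste(missing, collapse = ", ")), class = "ciliadyn_parse_error")
  }
  for (col in names(schema)) {
    type <- schema[[col]]
    if (type %in% c("numeric", "integer")) {
      vals <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(vals) & !is.na(df[[col]]))
      if (length(bad) > 0) {
        abort(sprintf(
          "%s file %s: non-numeric value '%s' in column '%s' at data line %d",
          what, path, df[[col]][bad[1]], col, bad[1] + 1L # +1 for the header line
        ), class = "ciliadyn_parse_error")
      }
      df[[col]] <- if (type == "integer") as.integer(round(vals)) else vals
    }
  }
  tibble::as_tibble(df[, union(names(schema), names(df))])
}

#' Read traced orientation vectors
#'
#' Reads a CSV of manually traced base-to-tip coordinate pairs (e.g. basal
#' rootlet to basal body lines). Required columns: `cell_id`, `base_x`,
#' `base_y`, `tip_x`, `tip_y`; extra columns such as `condition` are kept.
#'
#' @param path CSV file path.
#' @return A tibble, one traced vector per row.
#' @export
read_vectors <- function(path) {
  read_table_checked(path, c(cell_id = "character", base_x = "numeric",
    base_y = "numeric", tip_x = "numeric", tip_y = "numeric"), "orientation-vector")
}

#' Read cell-outline ROI polygons
#'
#' Required columns: `cell_id`, `vertex` (ordering index), `x`, `y`
#' (0-based pixel-centre coordinates). Each cell must contribute at least
#' three vertices.
#'
#' @param path CSV file path.
#' @return A tibble of polygon vertices.
#' @export
read_rois <- function(path) {
  df <- read_table_checked(path, c(cell_id = "character", vertex = "integer",
    x = "numeric", y = "numeric"), "ROI")
  counts <- table(df$cell_id)
  bad <- names(counts)[counts < 3]
  if (length(bad) > 0) {
    abort(sprintf("ROI polygons with fewer than 3 vertices: %s",
      paste(bad, collapse = ", ")), class = "ciliadyn_parse_error")
  }
  dplyr::arrange(df, .data$cell_id, .data$vertex)
}

#' Read bead-detection / track tables
#'
#' Required columns: `track_id`, `frame`, `x`, `y` (positions in µm).
#'
#' @param path CSV file path.
#' @return A tibble sorted by track and frame.
#' @export
read_tracks <- function(path) {
  df <- read_table_checked(path, c(track_id = "character", frame = "integer",
    x = "numeric", y = "numeric"), "track")
  dplyr::arrange(df, .data$track_id, .data$frame)
}

#' Read a LUMIER screen table
#'
#' Required columns: `prey`, `lir_rep1`, `lir_rep2` — one luminescence
#' intensity ratio per biological replicate screen.
#'
#' @param path CSV file path.
#' @return A tibble, one prey per row.
#' @export
read_lumier <- function(path) {
  read_table_checked(path, c(prey = "character", lir_rep1 = "numeric",
    lir_rep2 = "numeric"), "LUMIER")
}

#' Write a results table deterministically
#'
#' Writes a CSV with stable column order, rows sorted by the leading
#' (non-numeric, then all) columns, and floating-point values at 6
#' significant digits, so that identical inputs give byte-identical files.
#'
#' @param records A data frame.
#' @param path Output CSV path.
#' @param sort_by Columns to sort rows by; defaults to all columns in order.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, sort_by = names(records)) {
  assert_that(is.data.frame(records), "records must be a data frame")
  df <- tibble::as_tibble(records)
  if (nrow(df) > 0 && length(sort_by) > 0) {
    df <- dplyr::arrange(df, dplyr::across(dplyr::all_of(sort_by)))
  }
  out <- dplyr::mutate(df, dplyr::across(
    dplyr::where(is.double),
    ~ formatC(.x, digits = 6, format = "g")
  ))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write / read generator ground truth as JSON
#'
#' Serialises the ground-truth component of a synthetic field (see
#' [generate_cilia_field()]) so recovery tests can run against files on disk.
#'
#' @param truth Ground-truth tibble (list-columns are preserved).
#' @param path JSON path.
#' @return `path` invisibly; `read_ground_truth()` returns the tibble.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  df <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  tibble::as_tibble(df)
}

# --- configuration -----------------------------------------------------------

#' Default analysis configuration
#'
#' All tunable thresholds of the pipeline with their defaults. The source
#' study's high-content script parameters were not published; these defaults
#' are calibrated against the package's synthetic data (see the methods
#' vignette). `pixel_size_um` has no default on purpose: the acquisition
#' pixel size is never stated in the source protocol and must always come
#' from image metadata or the user.
#'
#' @return A named list of parameters.
#' @export
default_config <- function() {
  list(
    pixel_size_um = NA_real_, # required input, never defaulted
    spot_sigma_px = 2,
    min_peak_snr = 8,
    min_separation_px = 5,
    crop_side_um = 11,
    seed_quantile = 0.99,
    min_seed_px = 3,
    contrast_stop_ratio = 1.5,
    max_grow_iterations = 50,
    min_cilium_length_um = 1.0,
    adaptive_window_px = 51,
    adaptive_offset = 0,
    min_net_disp_um = 0.1,
    frame_interval_s = 1 / 37,
    lumier_threshold = 3,
    rose_bins = 24
  )
}

#' Read a flat key:value configuration file
#'
#' Parses the `key: value` subset of YAML (one setting per line, `#`
#' comments allowed). Unknown keys are rejected; every value is checked to
#' be numeric. Values merge over [default_config()].
#'
#' @param path Config file path.
#' @return A full configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path), class = "ciliadyn_io_error")
  }
  defaults <- default_config()
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) {
      abort(sprintf("config line %d is not 'key: value': '%s'", i, lines[i]),
        class = "ciliadyn_parse_error")
    }
    key <- trimws(parts[1])
    if (!key %in% names(defaults)) {
      abort(sprintf("unknown config key '%s' (line %d)", key, i),
        class = "ciliadyn_parse_error")
    }
    val <- suppressWarnings(as.numeric(trimws(parts[2])))
    if (is.na(val)) {
      abort(sprintf("config key '%s' has non-numeric value '%s'", key,
        trimws(parts[2])), class = "ciliadyn_parse_error")
    }
    defaults[[key]] <- val
  }
  defaults
}
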