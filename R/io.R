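#' Read digitized fascicle traces from CSV
#'
#' The canonical interchange format is one row per digitized point with columns
#' `fascicle_id, point_index, x_mm, y_mm, z_mm`. An optional companion landmarks
#' file (`name,x_mm,y_mm,z_mm`, with names `origin` and `insertion` for the
#' muscle-tendon-complex endpoints) attaches as the `landmarks` attribute.
#' Traces with fewer than 3 points cannot support quadratic smoothing and are
#' dropped with a warning.
#'
#' @param path Path to the fascicle point CSV.
#' @param landmarks_path Optional path to a landmarks CSV.
#' @param metadata Optional named list (age_d, animal_mass_kg, joint angles, ...)
#'   stored as the `metadata` attribute.
#' @return A tibble of fascicle points ordered by fascicle and `point_index`,
#'   with optional `landmarks` and `metadata` attributes.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' pts <- simulate_muscle(n_fascicles = 6, seed = 1)$points
#' write_fascicle_csv(pts, f)
#' head(read_fascicle_csv(f))
read_fascicle_csv <- function(path, landmarks_path = NULL, metadata = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         comment = "#",
                         col_types = readr::cols(.default = readr::col_character()))
  if (ncol(raw) == 0) abort(sprintf("empty fascicle file: %s", path))
  missing <- setdiff(POINT_COLS, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("fascicle CSV is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (nrow(raw) == 0) abort(sprintf("empty fascicle file: %s", path))
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) | is.na(raw[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric value in column `%s` at data row %d", col, bad[1]))
    }
    v
  }
  pts <- tibble::tibble(
    fascicle_id = as.character(raw$fascicle_id),
    point_index = as.integer(num("point_index")),
    x_mm = num("x_mm"), y_mm = num("y_mm"), z_mm = num("z_mm")
  )
  counts <- table(pts$fascicle_id)
  short <- names(counts)[counts < 3]
  if (length(short) > 0) {
    warn(sprintf("dropping %d trace(s) with fewer than 3 points: %s",
                 length(short), paste(short, collapse = ", ")))
    pts <- pts[!pts$fascicle_id %in% short, , drop = FALSE]
  }
  if (nrow(pts) == 0) abort("no usable fascicle traces (all had < 3 points)")
  ids <- unique(pts$fascicle_id)
  pts <- pts[order(match(pts$fascicle_id, ids), pts$point_index), , drop = FALSE]
  landmarks <- NULL
  if (!is.null(landmarks_path)) {
    lm <- readr::read_csv(landmarks_path, show_col_types = FALSE,
                          progress = FALSE, comment = "#")
    need <- c("name", "x_mm", "y_mm", "z_mm")
    if (!all(need %in% names(lm))) {
      abort(sprintf("landmarks CSV is missing column(s): %s",
                    paste(setdiff(need, names(lm)), collapse = ", ")))
    }
    landmarks <- tibble::as_tibble(lm[, need])
  }
  set_muscle_attrs(tibble::as_tibble(pts), landmarks = landmarks,
                   metadata = metadata)
}

#' Write fascicle traces (and optional landmarks) to CSV
#'
#' @param points Fascicle point tibble.
#' @param path Output CSV path.
#' @param landmarks_path Optional path for the landmarks companion CSV; defaults
#'   to writing nothing. When `NULL` and `points` carries landmarks they are not
#'   written.
#' @return `path`, invisibly.
#' @export
write_fascicle_csv <- function(points, path, landmarks_path = NULL) {
  check_points_df(points)
  readr::write_csv(points[, POINT_COLS], path, progress = FALSE)
  if (!is.null(landmarks_path)) {
    lm <- muscle_landmarks(points)
    if (is.null(lm)) abort("`points` carries no landmarks to write")
    readr::write_csv(lm, landmarks_path, progress = FALSE)
  }
  invisible(path)
}

#' Read or write a whole muscle dataset as a single JSON document
#'
#' JSON bundles the fascicle polylines, the optional muscle-tendon-complex
#' landmarks, and metadata in one self-describing document.
#'
#' @param points Fascicle point tibble (with optional attributes).
#' @param path File path.
#' @return `read_muscle_json()` returns the points tibble with attributes;
#'   `write_muscle_json()` returns `path` invisibly.
#' @export
write_muscle_json <- function(points, path) {
  check_points_df(points)
  mats <- fascicle_split(points)
  doc <- list(
    format = "pennate-muscle",
    version = as.character(utils::packageVersion("pennate")),
    units = "mm",
    fascicles = lapply(names(mats), function(id) {
      list(fascicle_id = id, points = unname(mats[[id]]))
    }),
    landmarks = muscle_landmarks(points),
    metadata = muscle_metadata(points)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_muscle_json
#' @export
read_muscle_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  fas <- doc$fascicles
  if (is.null(fas) || length(fas) == 0) abort("JSON document contains no fascicles")
  if (is.data.frame(fas)) {
    ids <- as.character(fas$fascicle_id)
    mats <- lapply(fas$points, function(m) matrix(as.numeric(m), ncol = 3))
  } else {
    ids <- vapply(fas, function(f) as.character(f$fascicle_id), character(1))
    mats <- lapply(fas, function(f) matrix(as.numeric(f$points), ncol = 3))
  }
  names(mats) <- ids
  out <- fascicles_to_tbl(mats)
  lm <- doc$landmarks
  if (!is.null(lm) && length(lm) > 0) {
    out <- set_muscle_attrs(out, landmarks = tibble::as_tibble(lm))
  }
  md <- doc$metadata
  if (!is.null(md) && length(md) > 0) out <- set_muscle_attrs(out, metadata = md)
  out
}

# Canonical flat field order for summary serialization (Table-style, units in
# the header names).
SUMMARY_FIELDS <- c(
  "n_fascicles",
  "belly_length_mm", "belly_width_mm",
  "fascicle_length_mean_mm", "fascicle_length_sd_mm",
  "pennation_mean_deg", "pennation_sd_deg",
  "transversal_mean_deg", "transversal_sd_deg",
  "aponeurosis_length_a_mm", "aponeurosis_length_b_mm", "aponeurosis_length_mm",
  "aponeurosis_width_a_mm", "aponeurosis_width_b_mm", "aponeurosis_width_mm",
  "muscle_height_mm", "muscle_volume_mm3", "muscle_mass_g", "pcsa_mm2",
  "free_tendon_mm"
)

#' Write an architecture summary to disk
#'
#' Serializes the flat key/value summary of [measure_architecture()] either as a
#' one-row CSV (units suffixed in the headers) or as a JSON object. A missing
#' optional field (e.g. free tendon length without landmarks) is emitted as
#' empty/null, never as 0.
#'
#' @param summary A `muscle_architecture` object or its [glance()] tibble.
#' @param path Output path.
#' @param format `"csv"` or `"json"`; default guessed from the file extension.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path, format = NULL) {
  g <- if (inherits(summary, "muscle_architecture")) glance(summary) else
    tibble::as_tibble(summary)
  if (nrow(g) != 1) abort("summary must be a single-row table")
  for (f in setdiff(SUMMARY_FIELDS, names(g))) g[[f]] <- NA_real_
  g <- g[, SUMMARY_FIELDS]
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    readr::write_csv(g, path, na = "", progress = FALSE)
  } else {
    jsonlite::write_json(as.list(g), path, auto_unbox = TRUE, digits = NA,
                         na = "null", null = "null")
  }
  invisible(path)
}

#' @rdname write_summary
#' @export
read_summary <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    g <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         comment = "#")
  } else {
    lst <- jsonlite::read_json(path, simplifyVector = TRUE)
    lst <- lapply(lst, function(x) if (is.null(x)) NA_real_ else as.numeric(x))
    g <- tibble::as_tibble(lst)
  }
  for (f in setdiff(SUMMARY_FIELDS, names(g))) g[[f]] <- NA_real_
  g <- g[, SUMMARY_FIELDS]
  g[] <- lapply(g, as.numeric)
  g
}
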