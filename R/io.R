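#' Write / read a scan-geometry sidecar
#'
#' Scan geometry travels next to image and label stacks as a small JSON
#' sidecar.
#'
#' @param geometry A [scan_geometry()].
#' @param path JSON file path.
#' @return `write_scan_geometry()` returns `path` invisibly;
#'   `read_scan_geometry()` returns a `scan_geometry`.
#' @export
write_scan_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "scan_geometry"))
  jsonlite::write_json(unclass(geometry), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scan_geometry
#' @export
read_scan_geometry <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(scan_geometry, g[c("n_bscans", "ascans_per_bscan", "axial_px",
                             "scan_length_mm", "bscan_spacing_um",
                             "scan_depth_mm", "fov_deg")])
}

#' Write a B-scan stack as grayscale PNG images
#'
#' One 8-bit grayscale PNG per B-scan, named `bscan_000.png`,
#' `bscan_001.png`, ... (zero-padded, lexicographically ordered), plus a
#' `geometry.json` sidecar.
#'
#' @param stack A `bscan_stack`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_bscan_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "bscan_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(stack$images)) {
    png::writePNG(round(stack$images[[i]]) / 255,
                  file.path(dir, sprintf("bscan_%03d.png", i - 1)))
  }
  write_scan_geometry(stack$geometry, file.path(dir, "geometry.json"))
  invisible(dir)
}

#' Read a B-scan stack from a directory of grayscale images
#'
#' Images are loaded in lexicographic filename order and converted to
#' single-channel 0-255 matrices. The stack is validated against the
#' geometry: the image count must equal `n_bscans` and every image must be
#' `axial_px` x `ascans_per_bscan`; violations name the offending file.
#'
#' @param path Directory containing the PNG images.
#' @param geometry A [scan_geometry()]; if NULL, read from the directory's
#'   `geometry.json` sidecar.
#' @return A `bscan_stack`.
#' @export
read_bscan_stack <- function(path, geometry = NULL) {
  if (is.null(geometry)) {
    sidecar <- file.path(path, "geometry.json")
    if (!file.exists(sidecar)) {
      stop("no geometry supplied and no geometry.json sidecar in ", path,
           call. = FALSE)
    }
    geometry <- read_scan_geometry(sidecar)
  }
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) != geometry$n_bscans) {
    stop(sprintf("expected %d B-scan images in %s, found %d",
                 geometry$n_bscans, path, length(files)), call. = FALSE)
  }
  imgs <- lapply(files, function(f) {
    img <- tryCatch(png::readPNG(f),
                    error = function(e) stop("unreadable image: ", f, call. = FALSE))
    if (length(dim(img)) == 3) img <- img[, , 1]
    if (nrow(img) != geometry$axial_px || ncol(img) != geometry$ascans_per_bscan) {
      stop(sprintf("image %s is %d x %d, expected %d x %d", basename(f),
                   nrow(img), ncol(img), geometry$axial_px,
                   geometry$ascans_per_bscan), call. = FALSE)
    }
    round(img * 255)
  })
  structure(list(images = imgs, geometry = geometry), class = "bscan_stack")
}

#' Write / read a label volume as a PNG raster stack
#'
#' Labels (1 = vitreous .. 4 = sclera) are stored one 8-bit grayscale PNG
#' per B-scan (raw label value as gray level) with a `geometry.json`
#' sidecar; exact round trip.
#'
#' @param volume A `label_volume`.
#' @param dir Directory.
#' @return `write_label_volume()` returns `dir` invisibly;
#'   `read_label_volume()` returns a `label_volume`.
#' @export
write_label_volume <- function(volume, dir) {
  stopifnot(inherits(volume, "label_volume"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nb <- dim(volume$labels)[3]
  for (i in seq_len(nb)) {
    png::writePNG(volume$labels[, , i] / 255,
                  file.path(dir, sprintf("labels_%03d.png", i - 1)))
  }
  write_scan_geometry(volume$geometry, file.path(dir, "geometry.json"))
  invisible(dir)
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(dir) {
  geometry <- read_scan_geometry(file.path(dir, "geometry.json"))
  files <- sort(list.files(dir, pattern = "^labels_.*\\.png$", full.names = TRUE))
  if (length(files) != geometry$n_bscans) {
    stop(sprintf("expected %d label images, found %d", geometry$n_bscans,
                 length(files)), call. = FALSE)
  }
  labels <- array(NA_integer_,
                  c(geometry$axial_px, geometry$ascans_per_bscan, geometry$n_bscans))
  for (i in seq_along(files)) {
    img <- png::readPNG(files[i])
    if (length(dim(img)) == 3) img <- img[, , 1]
    labels[, , i] <- as.integer(round(img * 255))
  }
  if (!all(labels %in% tissue_labels())) {
    stop("label stack contains values outside the 4-class label set", call. = FALSE)
  }
  new_label_volume(labels, geometry)
}

# canonical cohort CSV schema
cohort_columns <- function() {
  c("animal_id", "eye", "sex", "origin", "age_months", "weight_kg", region_ids())
}

#' Write a cohort table to the canonical CSV schema
#'
#' Columns: `animal_id, eye, sex, origin, age_months, weight_kg, Z1..Z3,
#' Q1..Q4, S1..S9` with volumes in mm^3 at 9 decimal places (so that a
#' write/read round trip is the identity to better than 1e-9 mm^3).
#'
#' @param cohort Cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  out <- cohort
  for (col in c("age_months", "weight_kg")) {
    if (!col %in% names(out)) out[[col]] <- NA_real_
  }
  missing <- setdiff(c("animal_id", "eye", "sex", "origin", region_ids()), names(out))
  if (length(missing)) {
    stop("cohort lacks columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- out[cohort_columns()]
  for (r in region_ids()) out[[r]] <- sprintf("%.9f", out[[r]])
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a cohort table, normalising a foreign schema
#'
#' Reads a delimited per-eye volume table into the canonical cohort tibble.
#' `column_map` maps canonical names to the file's headers for foreign
#' schemas (e.g. `list(animal_id = "Animal", S1 = "slice1")`). Values are
#' normalised: eye to OD/OS (accepting right/left, R/L, case-insensitive),
#' sex to male/female (accepting m/f), origin case-insensitively to
#' Mauritius/Asia with anything else mapped to unknown. Rows whose volume
#' fields do not parse as numbers are rejected and returned in the
#' `rejected` attribute with row-level diagnostics; no row is dropped
#' silently. If only slice columns are present, zones and quadrants are
#' reconstructed from the grid composition rule; if both are present their
#' consistency is checked to 1e-6 mm^3.
#'
#' @param path Delimited text file.
#' @param column_map Named list/character mapping canonical column names to
#'   file headers; NULL if the file already uses canonical names.
#' @param grid A [grid_spec()] used to reconstruct zones/quadrants.
#' @return Cohort tibble with attributes `rejected` (tibble of rejected rows
#'   with a `reason` column) and `n_input`.
#' @export
read_cohort_table <- function(path, column_map = NULL, grid = grid_spec()) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!is.null(column_map)) {
    cm <- unlist(column_map)
    missing_src <- setdiff(unname(cm), names(raw))
    if (length(missing_src)) {
      stop("column_map refers to absent file columns: ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    }
    names(raw)[match(unname(cm), names(raw))] <- names(cm)
  }
  mandatory <- c("animal_id", "eye", "sex", "origin", slice_ids()[-1])
  s1_ok <- "S1" %in% names(raw) || "Z1" %in% names(raw)
  missing <- setdiff(mandatory, names(raw))
  if (!s1_ok) missing <- c("S1 (or Z1)", missing)
  if (length(missing)) {
    stop("cohort table lacks mandatory columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"S1" %in% names(raw)) raw$S1 <- raw$Z1   # Z1 and S1 are the same volume

  vol_cols <- intersect(region_ids(), names(raw))
  parsed <- raw
  for (col in vol_cols) parsed[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  bad <- rowSums(is.na(parsed[vol_cols]) & !is.na(raw[vol_cols]) &
                   raw[vol_cols] != "") > 0 |
    rowSums(is.na(parsed[slice_ids()])) > 0
  rejected <- raw[bad, , drop = FALSE]
  if (nrow(rejected)) {
    rejected$reason <- "unparseable or missing volume"
  } else {
    rejected$reason <- character(0)
  }
  parsed <- parsed[!bad, , drop = FALSE]

  norm_eye <- function(x) {
    x <- toupper(trimws(x))
    dplyr::case_when(x %in% c("OD", "R", "RIGHT") ~ "OD",
                     x %in% c("OS", "L", "LEFT") ~ "OS",
                     TRUE ~ NA_character_)
  }
  norm_sex <- function(x) {
    x <- tolower(trimws(x))
    dplyr::case_when(x %in% c("m", "male") ~ "male",
                     x %in% c("f", "female") ~ "female",
                     TRUE ~ NA_character_)
  }
  norm_origin <- function(x) {
    x <- tolower(trimws(x))
    dplyr::case_when(x %in% c("mauritius", "mauritian") ~ "Mauritius",
                     x %in% c("asia", "asian") ~ "Asia",
                     TRUE ~ "unknown")
  }
  parsed$eye <- norm_eye(parsed$eye)
  parsed$sex <- norm_sex(parsed$sex)
  parsed$origin <- norm_origin(parsed$origin)

  S <- as.matrix(parsed[slice_ids()])
  A <- region_composition_matrix(grid)
  derived <- S %*% t(A)
  have_zq <- setdiff(vol_cols, slice_ids())
  for (col in have_zq) {
    delta <- max(abs(parsed[[col]] - derived[, col]), 0)
    if (delta > 1e-6) {
      stop(sprintf(
        "column %s inconsistent with slice composition (max |delta| = %.3g mm^3)",
        col, delta), call. = FALSE)
    }
  }
  for (col in setdiff(region_ids(), vol_cols)) parsed[[col]] <- derived[, col]

  for (col in c("age_months", "weight_kg")) {
    parsed[[col]] <- if (col %in% names(raw)) {
      suppressWarnings(as.numeric(parsed[[col]]))
    } else NA_real_
  }
  dup <- duplicated(parsed[c("animal_id", "eye")])
  if (any(dup)) {
    stop("duplicate (animal_id, eye) pairs in cohort table", call. = FALSE)
  }
  out <- tibble::as_tibble(parsed[cohort_columns()])
  attr(out, "rejected") <- tibble::as_tibble(rejected)
  attr(out, "n_input") <- nrow(raw)
  out
}
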