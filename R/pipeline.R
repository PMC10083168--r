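#' Pipeline configuration
#'
#' One declarative object holding every tunable of the two end-to-end paths:
#' scan geometry, measurement grid, nulla-search options, segmentation class
#' intensities, statistics options and the seed. Serialises to JSON with
#' [write_pipeline_config()] so a run is reproducible from its config alone.
#'
#' @param geometry A [scan_geometry()].
#' @param grid A [grid_spec()].
#' @param search_radius_mm,smoothing_window Nulla search, see [find_nulla()].
#' @param class_intensities Segmentation class means, see [segment_bscan()].
#' @param manova_drop_interaction_at,anova_drop_interaction_at Interaction
#'   retention levels for [manova_slices()] / [anova_per_slice()].
#' @param correlation_eyes Eye pooling for [correlation_block_summary()].
#' @param seed Integer seed for any stochastic stage.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(geometry = scan_geometry(), grid = grid_spec(),
                            search_radius_mm = 1.5, smoothing_window = 5,
                            class_intensities = default_class_intensities(),
                            manova_drop_interaction_at = 0.01,
                            anova_drop_interaction_at = 0.01 / 9,
                            correlation_eyes = "both",
                            seed = 1L) {
  stopifnot(inherits(geometry, "scan_geometry"), inherits(grid, "grid_spec"),
            search_radius_mm > 0, smoothing_window %% 2 == 1,
            length(class_intensities) == 4)
  structure(list(geometry = geometry, grid = grid,
                 search_radius_mm = search_radius_mm,
                 smoothing_window = smoothing_window,
                 class_intensities = class_intensities,
                 manova_drop_interaction_at = manova_drop_interaction_at,
                 anova_drop_interaction_at = anova_drop_interaction_at,
                 correlation_eyes = correlation_eyes,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- config
  x$geometry <- unclass(x$geometry)
  x$grid <- unclass(x$grid)
  # named vectors would serialise as bare arrays; keep the inner/outer keys
  x$grid$sector_slices <- lapply(x$grid$sector_slices, as.list)
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- do.call(scan_geometry, x$geometry)
  gr <- grid_spec(roi_diameter_um = x$grid$roi_diameter_um,
                  ring_diameters_mm = x$grid$ring_diameters_mm,
                  laterality_flip = x$grid$laterality_flip,
                  sector_slices = lapply(x$grid$sector_slices, function(s) {
                    c(inner = as.integer(s[["inner"]]), outer = as.integer(s[["outer"]]))
                  }))
  pipeline_config(geometry = g, grid = gr,
                  search_radius_mm = x$search_radius_mm,
                  smoothing_window = x$smoothing_window,
                  class_intensities = unlist(x$class_intensities),
                  manova_drop_interaction_at = x$manova_drop_interaction_at,
                  anova_drop_interaction_at = x$anova_drop_interaction_at,
                  correlation_eyes = x$correlation_eyes,
                  seed = x$seed)
}

#' Run the image path end to end
#'
#' For each input eye: load or accept its data (a `label_volume`, a
#' `bscan_stack`, or a directory containing either), segment if the input is
#' an intensity stack, then measure regional volumes with [process_eye()].
#' Per-eye failures are isolated: a failing eye is recorded in the failure
#' manifest and the remaining eyes still complete.
#'
#' @param inputs List of per-eye entries; each a list with one of `labels`
#'   (a `label_volume`), `stack` (a `bscan_stack`), `labels_dir` or
#'   `stack_dir` (paths), plus `eye` ("OD"/"OS") and optional metadata
#'   (`animal_id`, `sex`, `origin`, `age_months`, `weight_kg`).
#' @param config A [pipeline_config()].
#' @return Cohort tibble (one row per successful eye) with attribute
#'   `failures`: a tibble of `input`, `error` for the eyes that failed.
#' @export
run_image_pipeline <- function(inputs, config = pipeline_config()) {
  stopifnot(length(inputs) >= 1)
  rows <- list()
  failures <- list()
  for (i in seq_along(inputs)) {
    entry <- inputs[[i]]
    res <- tryCatch({
      # [[ indexing: $ would partial-match "stack" against "stack_dir"
      labels <- if (!is.null(entry[["labels"]])) {
        entry[["labels"]]
      } else if (!is.null(entry[["labels_dir"]])) {
        read_label_volume(entry[["labels_dir"]])
      } else {
        stack <- if (!is.null(entry[["stack"]])) entry[["stack"]] else
          read_bscan_stack(entry[["stack_dir"]])
        segment_stack(stack, config$class_intensities)
      }
      meas <- process_eye(labels, eye = entry$eye, grid = config$grid,
                          search_radius_mm = config$search_radius_mm,
                          smoothing_window = config$smoothing_window)
      dplyr::bind_cols(
        tibble::tibble(
          animal_id = entry$animal_id %||% sprintf("eye%03d", i),
          sex = entry$sex %||% NA_character_,
          origin = entry$origin %||% "unknown",
          age_months = entry$age_months %||% NA_real_,
          weight_kg = entry$weight_kg %||% NA_real_),
        meas)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <-
        tibble::tibble(input = i, error = conditionMessage(res))
    } else {
      rows[[length(rows) + 1]] <- res
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) out <- out[c(cohort_columns(),
                              setdiff(names(out), cohort_columns()))]
  attr(out, "failures") <- dplyr::bind_rows(failures)
  out
}

#' Run the statistics path
#'
#' Reads a cohort table (or accepts one in memory) and produces the full
#' reference-database report via [reproduce_report()].
#'
#' @param cohort A cohort tibble or a path to a canonical cohort CSV.
#' @param config A [pipeline_config()].
#' @return A `retvol_report`.
#' @export
run_reference_stats <- function(cohort, config = pipeline_config()) {
  if (is.character(cohort)) cohort <- read_cohort_table(cohort)
  reproduce_report(cohort)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
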