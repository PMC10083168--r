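#' Regional retinal volumes by voxel counting
#'
#' For every grid slice, counts the retina-labelled voxels in the A-scan
#' columns assigned to the slice (the full-depth cylinder through each
#' column) and multiplies by the physical voxel volume. Zones and quadrants
#' are derived by the grid's composition rule (Z1 = S1,
#' Z2 = S2+S3+S4+S5, Z3 = S6+S7+S8+S9, Q_k = S1/4 + inner + outer sector
#' slice), so the three partitions sum identically by construction.
#'
#' @param volume A `label_volume`.
#' @param masks A [build_region_masks()] result.
#' @param geometry A [scan_geometry()]; must match both inputs.
#' @return One-row tibble with Z1-Z3, Q1-Q4, S1-S9 in mm^3 and
#'   `clipped_fraction`.
#' @export
compute_region_volumes <- function(volume, masks, geometry = volume$geometry) {
  stopifnot(inherits(volume, "label_volume"), inherits(masks, "region_masks"))
  if (!identical(dim(volume$labels),
                 c(geometry$axial_px, geometry$ascans_per_bscan, geometry$n_bscans)) ||
      !identical(dim(masks$slice),
                 c(geometry$n_bscans, geometry$ascans_per_bscan))) {
    stop("label volume, masks and geometry dimensions do not match", call. = FALSE)
  }
  ret_count <- apply(volume$labels == tissue_labels()[["retina"]], c(2, 3), sum) # [x, b]
  slice_of_col <- t(masks$slice)                                                # [x, b]
  counts <- vapply(1:9, function(s) sum(ret_count[slice_of_col == s]), numeric(1))
  s <- counts * voxel_volume(geometry)
  names(s) <- slice_ids()
  region_volumes_row(s, masks$grid, clipped_fraction = masks$clipped_fraction)
}

#' Measure one eye end-to-end from a label volume
#'
#' Composition of the measurement stages: ILM extraction, nulla detection,
#' nulla-centered mask construction and voxel-count volumetry, plus label-map
#' QC. Pure: identical inputs give identical output.
#'
#' @param labels A `label_volume`.
#' @param eye `"OD"` or `"OS"`.
#' @param grid A [grid_spec()].
#' @param search_radius_mm,smoothing_window Nulla-search options, see
#'   [find_nulla()].
#' @return One-row tibble: regional volumes, `clipped_fraction`, the nulla
#'   position (`nulla_b`, `nulla_x`, `nulla_depth_px`) and QC counts
#'   (`n_out_of_order`, `n_zero_retina` summed over B-scans).
#' @export
process_eye <- function(labels, eye = c("OD", "OS"), grid = grid_spec(),
                        search_radius_mm = 1.5, smoothing_window = 5) {
  eye <- match.arg(eye)
  surface <- extract_ilm(labels)
  nulla <- find_nulla(surface, labels$geometry,
                      search_radius_mm = search_radius_mm,
                      smoothing_window = smoothing_window)
  masks <- build_region_masks(nulla, grid, labels$geometry, eye)
  vols <- compute_region_volumes(labels, masks, labels$geometry)
  qc <- validate_label_volume(labels)
  dplyr::bind_cols(
    vols,
    tibble::tibble(eye = eye,
                   nulla_b = nulla$b_index, nulla_x = nulla$x_index,
                   nulla_depth_px = nulla$depth_px,
                   n_out_of_order = sum(qc$n_out_of_order),
                   n_zero_retina = sum(qc$n_zero_retina))
  )
}
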