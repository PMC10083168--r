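#' Scan geometry of a raster OCT volume
#'
#' Describes the physical sampling of a rectangular raster OCT acquisition:
#' `n_bscans` horizontal B-scans of `ascans_per_bscan` A-scans each, every
#' A-scan digitised into `axial_px` depth pixels. Defaults reproduce a
#' 20-degree 25-line macular raster from a Heidelberg spectral-domain device
#' (25 lines at 221 um spacing, 512 x 496 px per B-scan, 5.3 mm scan length,
#' 1.9 mm scan depth).
#'
#' Pixel pitches follow from the physical extents: the lateral pitch is
#' `scan_length_mm / ascans_per_bscan`, the axial pitch
#' `scan_depth_mm / axial_px`, and the slow-axis pitch is `bscan_spacing_um`.
#'
#' @param n_bscans Number of B-scans in the raster.
#' @param ascans_per_bscan A-scans (columns) per B-scan.
#' @param axial_px Depth pixels per A-scan.
#' @param scan_length_mm Lateral extent of each B-scan in mm.
#' @param bscan_spacing_um Distance between adjacent B-scans in micrometres.
#' @param scan_depth_mm Axial extent of each A-scan in mm.
#' @param fov_deg Nominal field of view in degrees (informational).
#' @return An object of class `scan_geometry`.
#' @examples
#' g <- scan_geometry()
#' voxel_volume(g)
#' @export
scan_geometry <- function(n_bscans = 25, ascans_per_bscan = 512, axial_px = 496,
                          scan_length_mm = 5.3, bscan_spacing_um = 221,
                          scan_depth_mm = 1.9, fov_deg = 20) {
  counts <- c(n_bscans = n_bscans, ascans_per_bscan = ascans_per_bscan,
              axial_px = axial_px)
  if (any(counts < 2) || any(counts != round(counts))) {
    stop("n_bscans, ascans_per_bscan and axial_px must be integers >= 2",
         call. = FALSE)
  }
  lengths <- c(scan_length_mm = scan_length_mm,
               bscan_spacing_um = bscan_spacing_um,
               scan_depth_mm = scan_depth_mm)
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("scan_length_mm, bscan_spacing_um and scan_depth_mm must be > 0",
         call. = FALSE)
  }
  structure(
    list(
      n_bscans = as.integer(n_bscans),
      ascans_per_bscan = as.integer(ascans_per_bscan),
      axial_px = as.integer(axial_px),
      scan_length_mm = scan_length_mm,
      bscan_spacing_um = bscan_spacing_um,
      scan_depth_mm = scan_depth_mm,
      fov_deg = fov_deg
    ),
    class = "scan_geometry"
  )
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf(
    "<scan_geometry> %d B-scans x %d A-scans x %d px; %.3g mm x %.0f um x %.3g mm\n",
    x$n_bscans, x$ascans_per_bscan, x$axial_px,
    x$scan_length_mm, x$bscan_spacing_um, x$scan_depth_mm))
  invisible(x)
}

# pitches in mm; the slow axis is the B-scan spacing
lateral_pitch_mm <- function(geometry) geometry$scan_length_mm / geometry$ascans_per_bscan
axial_pitch_mm <- function(geometry) geometry$scan_depth_mm / geometry$axial_px
bscan_pitch_mm <- function(geometry) geometry$bscan_spacing_um / 1000

#' Physical volume of one voxel
#'
#' One voxel spans the lateral pixel pitch, the B-scan spacing (the slab each
#' raster line represents), and the axial pixel pitch. For the default
#' geometry this is (5.3/512) x 0.221 x (1.9/496) = 8.763e-6 mm^3.
#'
#' @param geometry A [scan_geometry()].
#' @return Voxel volume in mm^3.
#' @export
voxel_volume <- function(geometry) {
  stopifnot(inherits(geometry, "scan_geometry"))
  lateral_pitch_mm(geometry) * bscan_pitch_mm(geometry) * axial_pitch_mm(geometry)
}

# En-face coordinates of A-scan column centers, in mm from the scan corner.
# Columns are 1-based: A-scan ix spans [(ix-1)*pitch, ix*pitch), center at
# (ix - 0.5)*pitch; B-scan ib lies at (ib - 1)*spacing.
ascan_x_mm <- function(ix, geometry) (ix - 0.5) * lateral_pitch_mm(geometry)
bscan_y_mm <- function(ib, geometry) (ib - 1) * bscan_pitch_mm(geometry)

scan_center_mm <- function(geometry) {
  c(x = geometry$scan_length_mm / 2,
    y = (geometry$n_bscans - 1) / 2 * bscan_pitch_mm(geometry))
}

#' Measurement-grid specification
#'
#' The nulla-centered cylindrical grid: a disc of `roi_diameter_um` total
#' width partitioned into three concentric zones (ring diameters
#' `ring_diameters_mm`), four 90-degree quadrants bounded by the +-45-degree
#' diagonals, and nine slices: the central disc S1 (identical to zone 1),
#' four inner-ring sectors S2-S5 and four outer-ring sectors S6-S9.
#'
#' Sector naming: S2/S6 are the inner/outer superior sectors, S4/S8
#' inferior, S3/S7 nasal and S5/S9 temporal. Quadrants follow the same
#' sectors (Q1 superior, Q2 nasal, Q3 inferior, Q4 temporal), each taking a
#' quarter of S1 plus its inner and outer sector. Nasal/temporal mirror
#' between right (OD) and left (OS) eyes when `laterality_flip` is TRUE:
#' for OD the positive-x image direction is nasal, for OS temporal.
#'
#' @param roi_diameter_um Total grid width in micrometres.
#' @param ring_diameters_mm Strictly increasing ring diameters; the last one
#'   times 1000 must equal `roi_diameter_um`.
#' @param laterality_flip Mirror nasal/temporal between OD and OS.
#' @param sector_slices Named list mapping sectors to inner/outer slice
#'   numbers; defaults encode the naming above.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(roi_diameter_um = 3000,
                      ring_diameters_mm = c(1, 2, 3),
                      laterality_flip = TRUE,
                      sector_slices = list(
                        superior = c(inner = 2L, outer = 6L),
                        nasal    = c(inner = 3L, outer = 7L),
                        inferior = c(inner = 4L, outer = 8L),
                        temporal = c(inner = 5L, outer = 9L))) {
  if (any(diff(ring_diameters_mm) <= 0)) {
    stop("ring_diameters_mm must be strictly increasing", call. = FALSE)
  }
  if (!isTRUE(all.equal(ring_diameters_mm[length(ring_diameters_mm)] * 1000,
                        roi_diameter_um))) {
    stop("outermost ring diameter must equal roi_diameter_um", call. = FALSE)
  }
  stopifnot(length(ring_diameters_mm) == 3)
  slices <- sort(unlist(sector_slices))
  if (!identical(unname(slices), 2:9)) {
    stop("sector_slices must assign slices 2..9 exactly once", call. = FALSE)
  }
  structure(
    list(roi_diameter_um = roi_diameter_um,
         ring_diameters_mm = ring_diameters_mm,
         laterality_flip = isTRUE(laterality_flip),
         sector_slices = sector_slices),
    class = "grid_spec"
  )
}

# region id vectors used throughout
region_ids <- function() c(paste0("Z", 1:3), paste0("Q", 1:4), paste0("S", 1:9))
slice_ids <- function() paste0("S", 1:9)
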