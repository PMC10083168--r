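#' Extract the ILM surface from a label volume
#'
#' The inner limiting membrane (ILM) separates vitreous from retina; per
#' A-scan it is the first (shallowest) retina-labelled pixel. Columns with no
#' retina pixel are marked invalid and excluded from all downstream searches.
#'
#' @param volume A `label_volume`.
#' @return An `ilm_surface`: `depth` (B-scans x A-scans matrix of axial row
#'   indices), `valid` (logical matrix), and the geometry.
#' @export
extract_ilm <- function(volume) {
  stopifnot(inherits(volume, "label_volume"))
  d <- dim(volume$labels)
  ret <- volume$labels == tissue_labels()[["retina"]]
  depth <- matrix(NA_real_, d[3], d[2])      # [b, x]
  valid <- matrix(FALSE, d[3], d[2])
  for (ib in seq_len(d[3])) {
    sl <- ret[, , ib]
    any_ret <- colSums(sl) > 0
    first <- rep(NA_real_, d[2])
    first[any_ret] <- apply(sl[, any_ret, drop = FALSE], 2, which.max)
    depth[ib, ] <- first
    valid[ib, ] <- any_ret
  }
  if (!any(valid)) stop("no retina present in volume", call. = FALSE)
  structure(list(depth = depth, valid = valid, geometry = volume$geometry),
            class = "ilm_surface")
}

# Rolling median ignoring NA; odd window k (k = 1 disables).
roll_med <- function(v, k) {
  if (k <= 1) return(v)
  h <- k %/% 2
  n <- length(v)
  vapply(seq_len(n), function(i) {
    w <- v[max(1, i - h):min(n, i + h)]
    if (all(is.na(w))) NA_real_ else stats::median(w, na.rm = TRUE)
  }, numeric(1))
}

#' Locate the nulla (deepest ILM point)
#'
#' The nulla is the deepest point of the ILM within the foveolar depression:
#' the argmax of the axial row index ("deepest" is most posterior, i.e. the
#' largest row, since B-scans render vitreous at the top). The depth map is
#' median-smoothed first along each B-scan, then across B-scans, for
#' robustness to isolated segmentation errors. The search is restricted to a
#' disc of `search_radius_mm` about the scan center.
#'
#' Because depths are integer pixel rows, the smoothed maximum is typically a
#' plateau of tied columns rather than a single point. Ties are broken by
#' smallest en-face distance to the plateau centroid (the unbiased estimate
#' of the pit center; on a flat ILM the plateau spans the whole search disc,
#' so this reduces to the column nearest the scan center), then by smallest
#' distance to the scan center, then smallest B-scan index, then smallest
#' A-scan index.
#'
#' @param surface An [extract_ilm()] result.
#' @param geometry A [scan_geometry()] (defaults to the surface's own).
#' @param search_radius_mm Radius of the search disc about the scan center.
#' @param smoothing_window Odd median-filter window (1 disables smoothing).
#' @return A `nulla`: `b_index`, `x_index`, `depth_px`, and en-face `x_mm`,
#'   `y_mm` relative to the scan corner.
#' @export
find_nulla <- function(surface, geometry = surface$geometry,
                       search_radius_mm = 1.5, smoothing_window = 5) {
  stopifnot(inherits(surface, "ilm_surface"))
  if (smoothing_window %% 2 != 1) {
    stop("smoothing_window must be odd", call. = FALSE)
  }
  depth <- surface$depth
  depth[!surface$valid] <- NA_real_
  sm <- t(apply(depth, 1, roll_med, k = smoothing_window))
  sm <- apply(sm, 2, roll_med, k = smoothing_window)
  if (is.null(dim(sm))) sm <- matrix(sm, nrow = nrow(depth))

  ctr <- scan_center_mm(geometry)
  x <- ascan_x_mm(seq_len(ncol(sm)), geometry)
  y <- bscan_y_mm(seq_len(nrow(sm)), geometry)
  dist_ctr <- sqrt(outer((y - ctr[["y"]])^2, (x - ctr[["x"]])^2, `+`))
  in_window <- dist_ctr <= search_radius_mm & !is.na(sm)
  if (!any(in_window)) {
    stop("no valid ILM columns within the nulla search window", call. = FALSE)
  }
  sm[!in_window] <- -Inf
  best <- max(sm)
  cand <- which(sm == best, arr.ind = TRUE)     # [b, x]
  cx <- mean(x[cand[, 2]]); cy <- mean(y[cand[, 1]])
  dist_centroid <- sqrt((x[cand[, 2]] - cx)^2 + (y[cand[, 1]] - cy)^2)
  o <- order(dist_centroid, dist_ctr[cand], cand[, 1], cand[, 2])
  ib <- cand[o[1], 1]; ix <- cand[o[1], 2]
  structure(list(b_index = unname(ib), x_index = unname(ix),
                 depth_px = unname(surface$depth[ib, ix]),
                 x_mm = ascan_x_mm(ix, geometry),
                 y_mm = bscan_y_mm(ib, geometry)),
            class = "nulla")
}

#' @export
print.nulla <- function(x, ...) {
  cat(sprintf("<nulla> B-scan %d, A-scan %d, depth %g px (%.3f, %.3f) mm\n",
              x$b_index, x$x_index, x$depth_px, x$x_mm, x$y_mm))
  invisible(x)
}

#' Build the nulla-centered region masks
#'
#' Assigns every A-scan column to one of the nine grid slices (or outside)
#' by its en-face center: radius r from the nulla selects the ring
#' (r < 0.5 mm central disc S1, 0.5 <= r < 1.0 inner ring, 1.0 <= r < 1.5
#' outer ring, r >= 1.5 outside); the angle from the nulla selects the
#' sector, with quadrant boundaries on the +-45 degree diagonals. The first
#' B-scan is taken as superior; the positive lateral direction is nasal for
#' OD and temporal for OS (mirrored when the grid's `laterality_flip` is
#' set). All intervals are half-open for deterministic boundary assignment.
#'
#' @param nulla A [find_nulla()] result.
#' @param grid A [grid_spec()].
#' @param geometry A [scan_geometry()].
#' @param eye `"OD"` (right) or `"OS"` (left).
#' @return A `region_masks` object: `slice` (B-scans x A-scans integer
#'   matrix, 0 = outside, 1-9 = S1-S9), `sector` (0 outside ROI, 1-4
#'   following the quadrant order superior/nasal/inferior/temporal),
#'   `clipped_fraction`, and the inputs.
#' @export
build_region_masks <- function(nulla, grid, geometry, eye = c("OD", "OS")) {
  eye <- match.arg(eye)
  stopifnot(inherits(nulla, "nulla"), inherits(grid, "grid_spec"),
            inherits(geometry, "scan_geometry"))
  if (nulla$b_index < 1 || nulla$b_index > geometry$n_bscans ||
      nulla$x_index < 1 || nulla$x_index > geometry$ascans_per_bscan) {
    stop("nulla outside scan bounds", call. = FALSE)
  }
  radii <- grid$ring_diameters_mm / 2
  x <- ascan_x_mm(seq_len(geometry$ascans_per_bscan), geometry)
  y <- bscan_y_mm(seq_len(geometry$n_bscans), geometry)
  dx <- outer(rep(1, length(y)), x - nulla$x_mm)
  dy <- outer(y - nulla$y_mm, rep(1, length(x)))
  r <- sqrt(dx^2 + dy^2)

  ring <- matrix(0L, nrow(r), ncol(r))
  ring[r < radii[3]] <- 3L
  ring[r < radii[2]] <- 2L
  ring[r < radii[1]] <- 1L

  # angle: +x lateral, superior is the -y (first B-scan) direction
  theta <- (atan2(-dy, dx) * 180 / pi) %% 360
  sector_name <- matrix("", nrow(r), ncol(r))
  sector_name[theta >= 45 & theta < 135] <- "superior"
  sector_name[theta >= 225 & theta < 315] <- "inferior"
  east <- (theta >= 315 | theta < 45)
  west <- (theta >= 135 & theta < 225)
  nasal_is_east <- !grid$laterality_flip || eye == "OD"
  sector_name[east] <- if (nasal_is_east) "nasal" else "temporal"
  sector_name[west] <- if (nasal_is_east) "temporal" else "nasal"

  sector_order <- names(grid$sector_slices)
  sector <- matrix(match(sector_name, sector_order), nrow(r), ncol(r))
  sector[ring == 0L] <- 0L

  slice <- matrix(0L, nrow(r), ncol(r))
  slice[ring == 1L] <- 1L
  for (k in seq_along(sector_order)) {
    sl <- grid$sector_slices[[k]]
    slice[ring == 2L & sector == k] <- as.integer(sl[["inner"]])
    slice[ring == 3L & sector == k] <- as.integer(sl[["outer"]])
  }

  structure(list(slice = slice, sector = sector, ring = ring,
                 clipped_fraction = roi_clipped_fraction(nulla, radii[3], geometry),
                 nulla = nulla, grid = grid, geometry = geometry, eye = eye),
            class = "region_masks")
}

# Fraction of the ideal ROI footprint (column centers within the ROI radius
# on an unbounded grid of the same pitches) that falls outside the scan.
roi_clipped_fraction <- function(nulla, radius_mm, geometry) {
  lp <- lateral_pitch_mm(geometry); bp <- bscan_pitch_mm(geometry)
  ix <- seq(floor((nulla$x_mm - radius_mm) / lp), ceiling((nulla$x_mm + radius_mm) / lp))
  ib <- seq(floor((nulla$y_mm - radius_mm) / bp), ceiling((nulla$y_mm + radius_mm) / bp))
  xs <- (ix - 0.5) * lp
  ys <- (ib - 1) * bp
  r <- sqrt(outer((ys - nulla$y_mm)^2, (xs - nulla$x_mm)^2, `+`))
  inside_roi <- r < radius_mm
  in_scan <- outer(ib >= 1 & ib <= geometry$n_bscans,
                   ix >= 1 & ix <= geometry$ascans_per_bscan, `&`)
  1 - sum(inside_roi & in_scan) / sum(inside_roi)
}
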