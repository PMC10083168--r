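# Tissue label encoding used everywhere: vitreous above retina above choroid
# above sclera along each A-scan.
tissue_labels <- function() c(vitreous = 1L, retina = 2L, choroid = 3L, sclera = 4L)

#' Parameters of the digital foveal phantom
#'
#' The phantom models the macula as four stacked tissue layers. The inner
#' limiting membrane (ILM) carries a single Gaussian pit,
#' `depth(r) = z_base + pit_depth * exp(-r^2 / (2 * pit_sigma^2))`, with r the
#' en-face distance from the pit center (scan center plus
#' `pit_center_offset_mm`). Retinal thickness follows a radial profile,
#' linearly interpolated between the foveal value at r = 0, the parafoveal
#' value at r = 1 mm and the peripheral value at r = 2.5 mm (constant
#' beyond). The thickness defaults are calibrated so that the three zone
#' volumes of the default grid match the normative means 0.205, 0.768 and
#' 1.375 mm^3.
#'
#' @param pit_depth_um ILM elevation at the pit center vs. periphery (um).
#' @param pit_sigma_um Gaussian pit width (um).
#' @param thickness_fovea_um,thickness_para_um,thickness_peripheral_um
#'   Retinal thickness at r = 0, 1.0 and 2.5 mm (um); a foveal depression
#'   requires `thickness_fovea_um < thickness_para_um`.
#' @param outer_boundary_depth_px Axial row of the retina/choroid boundary at
#'   the scan periphery.
#' @param choroid_thickness_px,sclera_thickness_px Layer thickness in axial
#'   pixels (sclera extends at least this far; it fills the remaining rows).
#' @param pit_center_offset_mm Length-2 (x, y) displacement of the pit center
#'   from the scan center, in mm.
#' @param noise_sd Additive Gaussian intensity noise (0-255 scale) used by
#'   [render_bscan_images()].
#' @param seed Random seed for rendering noise.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(pit_depth_um = 120, pit_sigma_um = 400,
                           thickness_fovea_um = 212, thickness_para_um = 358,
                           thickness_peripheral_um = 312,
                           outer_boundary_depth_px = 300,
                           choroid_thickness_px = 40, sclera_thickness_px = 30,
                           pit_center_offset_mm = c(0, 0),
                           noise_sd = 10, seed = 1L) {
  th <- c(thickness_fovea_um, thickness_para_um, thickness_peripheral_um)
  if (any(th <= 0)) stop("retinal thicknesses must be > 0", call. = FALSE)
  if (thickness_fovea_um > thickness_para_um) {
    stop("thickness_fovea_um must be <= thickness_para_um (inverted foveal profile)",
         call. = FALSE)
  }
  if (pit_depth_um < 0 || pit_sigma_um <= 0) {
    stop("pit_depth_um must be >= 0 and pit_sigma_um > 0", call. = FALSE)
  }
  stopifnot(length(pit_center_offset_mm) == 2)
  structure(
    list(pit_depth_um = pit_depth_um, pit_sigma_um = pit_sigma_um,
         thickness_fovea_um = thickness_fovea_um,
         thickness_para_um = thickness_para_um,
         thickness_peripheral_um = thickness_peripheral_um,
         outer_boundary_depth_px = outer_boundary_depth_px,
         choroid_thickness_px = choroid_thickness_px,
         sclera_thickness_px = sclera_thickness_px,
         pit_center_offset_mm = as.numeric(pit_center_offset_mm),
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "phantom_params"
  )
}

# Continuous retinal thickness profile in mm at en-face radius r (mm).
phantom_thickness_mm <- function(r, params) {
  tf <- params$thickness_fovea_um / 1000
  tp <- params$thickness_para_um / 1000
  te <- params$thickness_peripheral_um / 1000
  ifelse(r <= 1, tf + (tp - tf) * r,
         ifelse(r <= 2.5, tp + (te - tp) * (r - 1) / 1.5, te))
}

# Continuous ILM depth in axial pixels at radius r (mm).
phantom_ilm_px <- function(r, params, geometry) {
  ax <- axial_pitch_mm(geometry)
  z_base <- params$outer_boundary_depth_px -
    params$thickness_peripheral_um / 1000 / ax
  sigma <- params$pit_sigma_um / 1000
  z_base + params$pit_depth_um / 1000 / ax * exp(-r^2 / (2 * sigma^2))
}

new_label_volume <- function(labels, geometry, truth = NULL) {
  stopifnot(length(dim(labels)) == 3)
  structure(list(labels = labels, geometry = geometry, truth = truth),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %d px x %d A-scans x %d B-scans\n", d[1], d[2], d[3]))
  invisible(x)
}

# En-face radius (mm) of every column from the phantom pit center; matrix
# [n_bscans, ascans].
enface_radius_from_pit <- function(geometry, params) {
  ctr <- scan_center_mm(geometry)
  cx <- ctr["x"] + params$pit_center_offset_mm[1]
  cy <- ctr["y"] + params$pit_center_offset_mm[2]
  x <- ascan_x_mm(seq_len(geometry$ascans_per_bscan), geometry)
  y <- bscan_y_mm(seq_len(geometry$n_bscans), geometry)
  sqrt(outer((y - cy)^2, (x - cx)^2, `+`))
}

#' Synthesize a labelled OCT phantom volume
#'
#' Builds a 3-D semantic label volume (vitreous/retina/choroid/sclera) whose
#' ILM surface carries the parametric foveal pit of `params`, together with
#' ground truth: the continuous ILM depth map, the pit center in physical
#' and index coordinates, and the per-column retinal thickness.
#'
#' @param geometry A [scan_geometry()].
#' @param params A [phantom_params()].
#' @return A `label_volume` whose `truth` element holds `ilm_px` (continuous
#'   depth map, B-scans x A-scans), `pit_center_mm`, `pit_center_index`
#'   (B-scan, A-scan) and `thickness_mm`.
#' @export
synthesize_label_volume <- function(geometry, params) {
  stopifnot(inherits(geometry, "scan_geometry"), inherits(params, "phantom_params"))
  ax <- axial_pitch_mm(geometry)
  r <- enface_radius_from_pit(geometry, params)       # [b, x]
  ilm_cont <- phantom_ilm_px(r, params, geometry)
  t_px <- phantom_thickness_mm(r, params) / ax

  ilm_row <- round(ilm_cont)
  n_ret <- pmax(round(t_px), 1)   # pmax keeps the matrix dims of its first arg
  chor_end <- ilm_row + n_ret + params$choroid_thickness_px
  deepest <- max(chor_end) + params$sclera_thickness_px
  if (deepest > geometry$axial_px) {
    stop(sprintf(paste0(
      "phantom layers exceed axial extent (%d px needed, %d available); ",
      "reduce outer_boundary_depth_px, thickness, choroid_thickness_px or ",
      "sclera_thickness_px"), as.integer(deepest), geometry$axial_px),
      call. = FALSE)
  }
  if (min(ilm_row) < 1) {
    stop("phantom ILM above the scan (outer_boundary_depth_px too small)",
         call. = FALSE)
  }

  nz <- geometry$axial_px; nx <- geometry$ascans_per_bscan; nb <- geometry$n_bscans
  labels <- array(tissue_labels()[["vitreous"]], dim = c(nz, nx, nb))
  z <- seq_len(nz)
  for (ib in seq_len(nb)) {
    ilm_b <- matrix(ilm_row[ib, ], nz, nx, byrow = TRUE)
    ret_b <- matrix(ilm_row[ib, ] + n_ret[ib, ], nz, nx, byrow = TRUE)
    cho_b <- matrix(chor_end[ib, ], nz, nx, byrow = TRUE)
    Z <- matrix(z, nz, nx)
    labels[, , ib] <- 1L + (Z >= ilm_b) + (Z >= ret_b) + (Z >= cho_b)
  }

  ctr <- scan_center_mm(geometry)
  pit_mm <- c(x = unname(ctr["x"]) + params$pit_center_offset_mm[1],
              y = unname(ctr["y"]) + params$pit_center_offset_mm[2])
  pit_idx <- c(b = round(pit_mm[["y"]] / bscan_pitch_mm(geometry) + 1),
               x = round(pit_mm[["x"]] / lateral_pitch_mm(geometry) + 0.5))
  new_label_volume(labels, geometry, truth = list(
    ilm_px = ilm_cont,
    thickness_mm = phantom_thickness_mm(r, params),
    pit_center_mm = pit_mm,
    pit_center_index = pit_idx,
    params = params
  ))
}

# Run code with a private RNG stream, restoring the caller's state.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Render grayscale B-scan images from a label volume
#'
#' Each tissue class is rendered at a distinct mean intensity (0-255 scale)
#' with additive Gaussian noise of scale `params$noise_sd`; deterministic
#' given `params$seed`.
#'
#' @param volume A `label_volume`.
#' @param params A [phantom_params()] (supplies `noise_sd` and `seed`).
#' @param class_intensities Named mean intensity per tissue class.
#' @return A `bscan_stack`: list of B-scan image matrices plus the geometry.
#' @export
render_bscan_images <- function(volume, params,
                                class_intensities = default_class_intensities()) {
  stopifnot(inherits(volume, "label_volume"))
  nb <- dim(volume$labels)[3]
  imgs <- with_local_seed(params$seed, {
    lapply(seq_len(nb), function(ib) {
      lab <- volume$labels[, , ib]
      img <- matrix(class_intensities[lab], nrow(lab), ncol(lab))
      if (params$noise_sd > 0) img <- img + rnorm(length(img), sd = params$noise_sd)
      pmin(pmax(img, 0), 255)
    })
  })
  structure(list(images = imgs, geometry = volume$geometry), class = "bscan_stack")
}

#' @export
print.bscan_stack <- function(x, ...) {
  cat(sprintf("<bscan_stack> %d B-scans of %d x %d px\n", length(x$images),
              nrow(x$images[[1]]), ncol(x$images[[1]])))
  invisible(x)
}

#' Analytic regional volumes of the phantom
#'
#' Independent oracle for the voxel-counting path: integrates the continuous
#' phantom thickness profile over each region footprint by fine radial
#' midpoint quadrature (step 0.25 um, far finer than the voxel grid). Valid
#' when the measurement grid is centered on the pit, in which case the
#' profile is radially symmetric and each ring splits equally across its
#' four sectors.
#'
#' @param geometry A [scan_geometry()] (unused except for validation; the
#'   oracle is continuous).
#' @param params A [phantom_params()].
#' @param grid A [grid_spec()].
#' @return One-row tibble with Z1-Z3, Q1-Q4, S1-S9 (mm^3) and
#'   `clipped_fraction = 0`.
#' @export
true_region_volumes <- function(geometry = scan_geometry(),
                                params = phantom_params(),
                                grid = grid_spec()) {
  radii <- grid$ring_diameters_mm / 2
  ring_integral <- function(r0, r1) {
    dr <- 0.00025
    r <- seq(r0 + dr / 2, r1 - dr / 2, by = dr)
    sum(2 * pi * r * phantom_thickness_mm(r, params)) * dr
  }
  s1 <- ring_integral(0, radii[1])
  inner <- ring_integral(radii[1], radii[2])
  outer <- ring_integral(radii[2], radii[3])
  s <- c(s1, rep(inner / 4, 4), rep(outer / 4, 4))
  names(s) <- slice_ids()
  region_volumes_row(s, grid, clipped_fraction = 0)
}

# Assemble the canonical one-row region-volume tibble from the nine slice
# volumes, deriving zones and quadrants by the grid's composition rule:
# Z1 = S1, Z2 = S2+S3+S4+S5, Z3 = S6+S7+S8+S9,
# Q_k = S1/4 + inner sector slice + outer sector slice.
region_volumes_row <- function(s, grid, clipped_fraction = 0) {
  stopifnot(identical(names(s), slice_ids()))
  q <- vapply(grid$sector_slices, function(sl) {
    s[["S1"]] / 4 + s[[paste0("S", sl[["inner"]])]] + s[[paste0("S", sl[["outer"]])]]
  }, numeric(1))
  tibble::tibble(
    Z1 = s[["S1"]],
    Z2 = sum(s[paste0("S", 2:5)]),
    Z3 = sum(s[paste0("S", 6:9)]),
    Q1 = q[[1]], Q2 = q[[2]], Q3 = q[[3]], Q4 = q[[4]],
    !!!as.list(s),
    clipped_fraction = clipped_fraction
  )
}
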