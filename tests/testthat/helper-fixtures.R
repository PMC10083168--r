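# Reduced-resolution geometry for fast unit tests: same physical extents as
# the device raster, fewer A-scans and depth pixels. 127 A-scans put a column
# center exactly at the lateral scan center, which keeps centered phantoms
# rotationally symmetric on the discrete grid.
small_geometry <- function(ascans = 127, axial = 200) {
  scan_geometry(n_bscans = 25, ascans_per_bscan = ascans, axial_px = axial)
}

# Phantom parameters that fit the reduced axial extent.
small_params <- function(...) {
  phantom_params(outer_boundary_depth_px = 120, choroid_thickness_px = 20,
                 sclera_thickness_px = 15, ...)
}

small_phantom <- function(geometry = small_geometry(), params = small_params()) {
  synthesize_label_volume(geometry, params)
}

# Flat-retina phantom: no pit, constant thickness.
flat_params <- function(thickness_um = 260, ...) {
  phantom_params(pit_depth_um = 0,
                 thickness_fovea_um = thickness_um,
                 thickness_para_um = thickness_um,
                 thickness_peripheral_um = thickness_um, ...)
}

# Hand-written region composition (independent of the package's internal
# matrix): zones and quadrants as linear combinations of the nine slices.
oracle_composition <- function() {
  A <- matrix(0, 16, 9,
              dimnames = list(c(paste0("Z", 1:3), paste0("Q", 1:4), paste0("S", 1:9)),
                              paste0("S", 1:9)))
  A["Z1", "S1"] <- 1
  A["Z2", c("S2", "S3", "S4", "S5")] <- 1
  A["Z3", c("S6", "S7", "S8", "S9")] <- 1
  A["Q1", c("S2", "S6")] <- 1; A["Q2", c("S3", "S7")] <- 1
  A["Q3", c("S4", "S8")] <- 1; A["Q4", c("S5", "S9")] <- 1
  A[paste0("Q", 1:4), "S1"] <- 1 / 4
  diag(A[paste0("S", 1:9), ]) <- 1
  A
}

expect_volumes_additive <- function(vols, tol = 1e-9) {
  s_sum <- sum(vols[paste0("S", 1:9)])
  q_sum <- sum(vols[paste0("Q", 1:4)])
  z_sum <- sum(vols[paste0("Z", 1:3)])
  expect_identical(vols$Z1, vols$S1)
  expect_lt(abs(s_sum - q_sum), tol)
  expect_lt(abs(s_sum - z_sum), tol)
}
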