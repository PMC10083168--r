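test_that("ILM depth is the first retina row; empty columns are invalid", {
  g <- scan_geometry(n_bscans = 2, ascans_per_bscan = 3, axial_px = 200)
  labels <- array(1L, dim = c(200, 3, 2))
  labels[100:160, 1, 1] <- 2L; labels[161:200, 1, 1] <- 3L
  labels[120:180, 2, 1] <- 2L; labels[181:200, 2, 1] <- 3L
  labels[50:90, , 2] <- 2L; labels[91:200, , 2] <- 3L
  labels[, 3, 2] <- 1L
  vol <- retvol:::new_label_volume(labels, g)
  surf <- extract_ilm(vol)
  expect_equal(surf$depth[1, 1], 100)
  expect_equal(surf$depth[1, 2], 120)
  expect_false(surf$valid[1, 3])
  expect_false(surf$valid[2, 3])
  expect_equal(surf$depth[2, 1], 50)
})

test_that("extract_ilm fails when no retina exists", {
  g <- small_geometry()
  vol <- retvol:::new_label_volume(array(1L, c(g$axial_px, g$ascans_per_bscan,
                                               g$n_bscans)), g)
  expect_error(extract_ilm(vol), "no retina")
})

test_that("recovered ILM matches phantom ground truth within one pixel", {
  vol <- small_phantom(params = small_params(pit_center_offset_mm = c(0.3, -0.4)))
  surf <- extract_ilm(vol)
  expect_true(all(abs(surf$depth - vol$truth$ilm_px) <= 1))
})

test_that("nulla lands on the pit for centered and offset phantoms", {
  g <- scan_geometry()
  vol <- synthesize_label_volume(g, phantom_params())
  nulla <- find_nulla(extract_ilm(vol))
  expect_equal(nulla$b_index, 13)
  expect_lte(abs(nulla$x_index - 256.5), 1)

  voff <- synthesize_label_volume(g, phantom_params(pit_center_offset_mm = c(0.4, 0.221)))
  noff <- find_nulla(extract_ilm(voff))
  truth <- voff$truth$pit_center_index
  expect_lte(abs(noff$b_index - truth[["b"]]), 1)
  expect_lte(abs(noff$x_index - truth[["x"]]), 1)
})

test_that("flat ILM tie-breaks to the column nearest the scan center", {
  g <- small_geometry()          # odd A-scan count: center column exists
  vol <- synthesize_label_volume(g, flat_params(
    260, outer_boundary_depth_px = 120, choroid_thickness_px = 20,
    sclera_thickness_px = 15))
  nulla <- find_nulla(extract_ilm(vol))
  expect_equal(c(nulla$b_index, nulla$x_index), c(13, 64))
})

test_that("median smoothing suppresses an isolated segmentation spike", {
  vol <- small_phantom()
  surf <- extract_ilm(vol)
  spiked <- surf
  spiked$depth[9, 50] <- spiked$depth[9, 50] + 60   # lone deep outlier off-center
  n <- find_nulla(spiked)
  expect_equal(n$b_index, 13)
  expect_lte(abs(n$x_index - 64), 1)
  # without smoothing the spike wins
  n_raw <- find_nulla(spiked, smoothing_window = 1)
  expect_equal(c(n_raw$b_index, n_raw$x_index), c(9, 50))
})

test_that("slices partition the ROI footprint exactly", {
  g <- small_geometry()
  vol <- small_phantom(g)
  nulla <- find_nulla(extract_ilm(vol))
  masks <- build_region_masks(nulla, grid_spec(), g, "OD")
  x <- retvol:::ascan_x_mm(seq_len(g$ascans_per_bscan), g)
  y <- retvol:::bscan_y_mm(seq_len(g$n_bscans), g)
  r <- sqrt(outer((y - nulla$y_mm)^2, (x - nulla$x_mm)^2, `+`))
  expect_true(all((masks$slice > 0) == (r < 1.5)))
  # disjoint by construction (single assignment matrix); all nine present
  expect_setequal(setdiff(unique(as.vector(masks$slice)), 0L), 1:9)
  expect_equal(masks$clipped_fraction, 0)
})

test_that("OD and OS swap nasal and temporal slices, superior/inferior fixed", {
  g <- small_geometry()
  nulla <- find_nulla(extract_ilm(small_phantom(g)))
  od <- build_region_masks(nulla, grid_spec(), g, "OD")
  os <- build_region_masks(nulla, grid_spec(), g, "OS")
  swap <- c(0L, 1L, 2L, 5L, 4L, 3L, 6L, 9L, 8L, 7L)   # S3<->S5, S7<->S9
  expect_identical(od$slice, matrix(swap[os$slice + 1L], nrow(os$slice)))
})

test_that("a centered grid is 180-degree rotation symmetric across opposite slices", {
  g <- small_geometry()          # nulla exactly at the grid center
  nulla <- find_nulla(extract_ilm(small_phantom(g)))
  masks <- build_region_masks(nulla, grid_spec(), g, "OD")
  counts <- table(factor(masks$slice, levels = 0:9))
  expect_equal(counts[["2"]], counts[["4"]])   # superior <-> inferior, inner
  expect_equal(counts[["3"]], counts[["5"]])   # nasal <-> temporal, inner
  expect_equal(counts[["6"]], counts[["8"]])
  expect_equal(counts[["7"]], counts[["9"]])
})

test_that("nulla recovery stays within one A-scan and one B-scan across offsets", {
  g <- small_geometry()
  for (ox in c(-0.8, 0, 0.8)) {
    for (oy in c(-0.8, 0, 0.8)) {
      vol <- small_phantom(g, small_params(pit_center_offset_mm = c(ox, oy)))
      n <- find_nulla(extract_ilm(vol))
      truth <- vol$truth$pit_center_index
      expect_lte(abs(n$b_index - truth[["b"]]), 1)
      expect_lte(abs(n$x_index - truth[["x"]]), 1)
    }
  }
})

test_that("off-grid nulla reports a clipped ROI", {
  g <- small_geometry()
  vol <- small_phantom(g, small_params(pit_center_offset_mm = c(0, 1.6)))
  n <- find_nulla(extract_ilm(vol), search_radius_mm = 2.5)
  masks <- build_region_masks(n, grid_spec(), g, "OD")
  expect_gt(masks$clipped_fraction, 0)
})
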