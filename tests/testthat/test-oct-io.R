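test_that("B-scan stacks round-trip through PNG bit-exactly", {
  vol <- small_phantom()
  stack <- render_bscan_images(vol, small_params(noise_sd = 8, seed = 5))
  dir <- withr::local_tempdir()
  write_bscan_stack(stack, dir)
  back <- read_bscan_stack(dir)
  expect_equal(lapply(stack$images, round), back$images)
  expect_equal(back$geometry$n_bscans, stack$geometry$n_bscans)
})

test_that("stack reading validates image count and dimensions", {
  vol <- small_phantom()
  stack <- render_bscan_images(vol, small_params(noise_sd = 0))
  dir <- withr::local_tempdir()
  write_bscan_stack(stack, dir)
  file.remove(file.path(dir, "bscan_012.png"))
  expect_error(read_bscan_stack(dir), "expected 25 B-scan images.*found 24")

  dir2 <- withr::local_tempdir()
  write_bscan_stack(stack, dir2)
  png::writePNG(matrix(0.5, 10, 10), file.path(dir2, "bscan_012.png"))
  expect_error(read_bscan_stack(dir2), "bscan_012.png.*10 x 10")
})

test_that("label volumes round-trip with geometry sidecar", {
  vol <- small_phantom()
  dir <- withr::local_tempdir()
  write_label_volume(vol, dir)
  back <- read_label_volume(dir)
  expect_identical(back$labels, vol$labels)
  expect_equal(back$geometry$bscan_spacing_um, vol$geometry$bscan_spacing_um)
})

test_that("cohort tables round-trip to better than 1e-9 mm^3", {
  co <- simulate_cohort(effect_design(n_animals = 20, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_table(co, path)
  back <- read_cohort_table(path)
  for (r in c(paste0("Z", 1:3), paste0("Q", 1:4), paste0("S", 1:9))) {
    expect_lt(max(abs(back[[r]] - co[[r]])), 1e-9)
  }
  expect_identical(back$eye, co$eye)
  expect_identical(back$origin, co$origin)
  # summary statistics survive the round trip
  expect_equal(summarize_volumes(back, "Z1"), summarize_volumes(co, "Z1"),
               tolerance = 1e-8)
})

test_that("an empty cohort writes a header-only file", {
  co <- simulate_cohort(effect_design(n_animals = 2))[0, ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_table(co, path)
  expect_equal(length(readLines(path)), 1)
})

test_that("readers reject bad rows with diagnostics, never silently", {
  co <- simulate_cohort(effect_design(n_animals = 5, seed = 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_table(co, path)
  lines <- readLines(path)
  lines[3] <- sub("^([^,]*,[^,]*,[^,]*,[^,]*,[^,]*,[^,]*,)[^,]*", "\\1not_a_number",
                  lines[3])
  writeLines(lines, path)
  back <- read_cohort_table(path)
  rej <- attr(back, "rejected")
  expect_equal(nrow(back) + nrow(rej), attr(back, "n_input"))
  expect_equal(nrow(rej), 1)
  expect_match(rej$reason, "unparseable")
})

test_that("foreign schemas map through column_map with value normalisation", {
  co <- simulate_cohort(effect_design(n_animals = 4, seed = 6))
  foreign <- co
  names(foreign)[names(foreign) == "animal_id"] <- "Animal"
  foreign$eye <- ifelse(foreign$eye == "OD", "right", "LEFT")
  foreign$sex <- toupper(substr(foreign$sex, 1, 1))
  foreign$origin <- toupper(foreign$origin)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(foreign, path)
  back <- read_cohort_table(path, column_map = list(animal_id = "Animal"))
  expect_setequal(unique(back$eye), c("OD", "OS"))
  expect_setequal(unique(back$sex), c("male", "female"))
  expect_true(all(back$origin %in% c("Mauritius", "Asia", "unknown")))
  expect_true(all(back$origin[foreign$origin == "MAURITIUS"] == "Mauritius"))
})

test_that("zones/quadrants are rebuilt from slices and cross-checked when present", {
  co <- simulate_cohort(effect_design(n_animals = 4, seed = 7))
  slim <- co[c("animal_id", "eye", "sex", "origin", paste0("S", 1:9))]
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(slim, path)
  back <- read_cohort_table(path)
  expect_equal(back$Z2, co$Z2, tolerance = 1e-9)
  expect_equal(back$Q4, co$Q4, tolerance = 1e-9)

  broken <- co
  broken$Z2 <- broken$Z2 + 1e-3
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(broken, path2)
  expect_error(read_cohort_table(path2), "Z2 inconsistent")
})

test_that("missing mandatory columns are named", {
  co <- simulate_cohort(effect_design(n_animals = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(co[setdiff(names(co), c("sex", "S4"))], path)
  expect_error(read_cohort_table(path), "sex.*S4|S4.*sex")
})
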