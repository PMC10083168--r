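make_cohort <- function(...) simulate_cohort(effect_design(...))

test_that("summary statistics use the sample standard deviation", {
  co <- make_cohort(n_animals = 5, slice_cv = rep(0, 9))
  co$Z1 <- rep(c(0.1, 0.2, 0.3), length.out = nrow(co))
  s <- summarize_volumes(co[1:3, ], "Z1")
  expect_equal(s$mean, 0.2)
  expect_equal(s$median, 0.2)
  expect_equal(s$std, 0.1)      # n-1 denominator
  expect_equal(s$cv, 0.5)

  const <- summarize_volumes(make_cohort(n_animals = 5, slice_cv = rep(0, 9)), "S3")
  expect_equal(const$std, 0)
  expect_equal(const$cv, 0)
  expect_equal(const$min, const$max)
})

test_that("grouped summaries cover only the groups that exist", {
  co <- make_cohort(n_animals = 40, seed = 21)
  co <- co[co$origin != "unknown", ]
  g <- summarize_volumes(co, "Z1", group_keys = c("eye", "sex", "origin"))
  expect_lte(nrow(g), 8)
  expect_equal(sum(g$count), nrow(co))
  expect_false(any(g$count == 0))
})

test_that("a single shared factor drives all correlations to one", {
  f <- exp(rnorm(50, sd = 0.1))
  co <- tibble::tibble(animal_id = as.character(1:50),
                       eye = rep(c("OD", "OS"), 25),
                       sex = "male", origin = "Asia")
  for (s in 1:9) co[[paste0("S", s)]] <- f * s
  A <- oracle_composition()
  reg <- as.matrix(co[paste0("S", 1:9)]) %*% t(A)   # columns named by region
  co <- dplyr::bind_cols(co[c("animal_id", "eye", "sex", "origin")],
                         tibble::as_tibble(reg))
  blocks <- correlation_block_summary(co)
  expect_true(all(abs(blocks$mean - 1) < 1e-12))
  expect_true(all(blocks$n_excluded == 0))
})

test_that("independent slices decorrelate at the sampling bound", {
  co <- make_cohort(n_animals = 5000, between_slice_corr = diag(9), icc = 0,
                    seed = 13)
  blocks <- correlation_block_summary(co)
  among <- blocks[blocks$block == "among_slices", ]
  expect_lt(abs(among$mean), 0.03)    # ~2/sqrt(n) at n = 10^4
  expect_equal(among$n_pairs, 36)
})

test_that("correlation block shapes match the region families", {
  blocks <- correlation_block_summary(make_cohort(n_animals = 50, seed = 14))
  expect_equal(blocks$n_pairs[match(
    c("among_zones", "among_quadrants", "among_slices", "zones_x_quadrants",
      "zones_x_slices", "quadrants_x_slices"), blocks$block)],
    c(3, 6, 36, 12, 27, 36))
  # Z1 and S1 are the same volume: their correlation is exactly 1
  zs <- blocks[blocks$block == "zones_x_slices", ]
  expect_equal(zs$max, 1)
})

test_that("zero-variance regions are excluded with a count, not propagated", {
  cv <- c(0.079, 0, 0.048, 0.063, 0.045, 0.054, 0.039, 0.055, 0.038)
  co <- make_cohort(n_animals = 30, slice_cv = cv, seed = 15)
  blocks <- correlation_block_summary(co)
  among <- blocks[blocks$block == "among_slices", ]
  expect_equal(among$n_excluded, 8)   # every pair involving the constant S2
  expect_false(any(is.na(among$mean)))
})

test_that("CV is invariant under rescaling of all volumes", {
  co <- make_cohort(n_animals = 40, seed = 16)
  scaled <- co
  for (r in c(paste0("Z", 1:3), paste0("Q", 1:4), paste0("S", 1:9))) {
    scaled[[r]] <- scaled[[r]] * 3.7
  }
  expect_equal(summarize_volumes(scaled, "S5")$cv, summarize_volumes(co, "S5")$cv)
})

test_that("PCA agrees with an SVD route and fixes its sign convention", {
  co <- make_cohort(n_animals = 200, seed = 17)
  p <- pca_slices(co, "OD")
  X <- as.matrix(co[co$eye == "OD", paste0("S", 1:9)])
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  expect_equal(p$eigenvalues, unname(pr$sdev)^2, tolerance = 1e-10)
  expect_equal(p$cumulative_fraction[9], 1, tolerance = 1e-12)
  expect_equal(sum(p$explained_fraction), 1, tolerance = 1e-12)
  for (j in 1:9) {
    expect_gt(p$coefficients[which.max(abs(p$coefficients[, j])), j], 0)
    expect_equal(sum(p$coefficients[, j]^2), 1, tolerance = 1e-12)
    expect_equal(unname(abs(p$coefficients[, j])), unname(abs(pr$rotation[, j])),
                 tolerance = 1e-8)
  }
  expect_error(pca_slices(co[1:5, ], "OD"), ">= 10")
})

test_that("near-isotropic slices spread explained variance evenly", {
  co <- make_cohort(n_animals = 4000, between_slice_corr = diag(9),
                    slice_means_mm3 = rep(0.2, 9), slice_cv = rep(0.05, 9),
                    icc = 0, seed = 18)
  p <- pca_slices(co, "OD")
  expect_true(all(abs(p$explained_fraction - 1 / 9) < 0.02))
})

test_that("MANOVA matches the car implementation (type II Wilks)", {
  co <- make_cohort(n_animals = 120,
                    sex_effect_mm3 = c(0, 0.005, 0, 0.005, 0, 0, 0, 0, 0),
                    origin_effect_mm3 = c(0.008, rep(0, 8)), seed = 19)
  m <- manova_slices(co, "OD")
  d <- retvol:::stats_frame(co, "OD")
  Y <- as.matrix(d[paste0("S", 1:9)])
  full <- stats::lm(Y ~ sex + origin, data = d)
  reduced <- list(sex = stats::lm(Y ~ origin, data = d),
                  origin = stats::lm(Y ~ sex, data = d))
  for (term in c("sex", "origin")) {
    row <- m$table[m$table$term == term, ]
    oracle <- stats::anova(full, reduced[[term]], test = "Wilks")
    expect_equal(row$wilks, oracle$Wilks[2], tolerance = 1e-10)
    expect_equal(row$statistic, oracle$`approx F`[2], tolerance = 1e-8)
    expect_equal(row$df1, oracle$`num Df`[2])
    expect_equal(row$df2, oracle$`den Df`[2])
    expect_equal(row$p.value, oracle$`Pr(>F)`[2], tolerance = 1e-10)
  }
  expect_true(m$interaction_dropped)
})

test_that("with one response, Wilks' F reduces to the univariate ANOVA F", {
  co <- make_cohort(n_animals = 80, origin_effect_mm3 = c(0.006, rep(0, 8)),
                    seed = 20)
  d <- retvol:::stats_frame(co, "OD")
  y <- d$S1
  qrs <- retvol:::design_qrs(d)
  rss_add <- sum(qr.resid(qrs$add, y)^2)
  rss_sex <- sum(qr.resid(qrs$sex, y)^2)
  lambda <- rss_add / rss_sex                 # E / (E + H) for p = 1
  f <- retvol:::wilks_to_f(lambda, p = 1, q = 1, v = nrow(d) - 3)
  a <- anova_per_slice(co, "OD")
  a_row <- a$table[a$table$slice == "S1" & a$table$term == "origin", ]
  expect_equal(unname(f$F), unname(a_row$statistic), tolerance = 1e-10)
  expect_equal(unname(f$p), unname(a_row$p.value), tolerance = 1e-12)
})

test_that("per-slice ANOVA matches car's type II sums of squares", {
  co <- make_cohort(n_animals = 120,
                    sex_effect_mm3 = c(0, 0.005, 0, 0.005, 0, 0, 0, 0, 0),
                    origin_effect_mm3 = c(0.008, rep(0, 8)), seed = 19)
  a <- anova_per_slice(co, "OD")
  d <- retvol:::stats_frame(co, "OD")
  for (s in c("S1", "S2", "S7")) {
    kept <- a$interaction_p[s] < a$drop_interaction_at
    form <- if (kept) stats::as.formula(paste(s, "~ sex * origin")) else
      stats::as.formula(paste(s, "~ sex + origin"))
    ca <- car::Anova(stats::lm(form, data = d), type = "II")
    for (term in c("sex", "origin")) {
      row <- a$table[a$table$slice == s & a$table$term == term, ]
      expect_equal(row$statistic, ca[term, "F value"], tolerance = 1e-8)
      expect_equal(row$p.value, ca[term, "Pr(>F)"], tolerance = 1e-10)
    }
  }
})

test_that("interaction handling follows the configured retention level", {
  co <- make_cohort(n_animals = 150, seed = 22)
  always <- anova_per_slice(co, "OD", drop_interaction_at = 1)
  expect_true(all(paste0("S", 1:9) %in%
                    always$table$slice[always$table$term == "sex:origin"]))
  never <- anova_per_slice(co, "OD", drop_interaction_at = 0)
  expect_false(any(never$table$term == "sex:origin"))
})

test_that("single-level factors are rejected by name", {
  co <- make_cohort(n_animals = 40, seed = 23)
  co$sex <- "male"
  expect_error(manova_slices(co, "OD"), "'sex'")
  co2 <- make_cohort(n_animals = 40, seed = 23)
  co2$origin <- "Mauritius"
  expect_error(anova_per_slice(co2, "OD"), "'origin'")
})

test_that("Bonferroni stars follow the divided significance levels", {
  expect_equal(bonferroni_stars(9.8e-6), "***")
  expect_equal(bonferroni_stars(3.0e-3), "*")
  expect_equal(bonferroni_stars(1.6e-4), "**")
  expect_equal(bonferroni_stars(0.05 / 9), "")      # strict inequality
  expect_equal(bonferroni_stars(c(1e-9, 0.2)), c("***", ""))
  expect_equal(bonferroni_stars(0.04, m = 1), "*")
})

test_that("the report degrades gracefully and summarises faithfully", {
  d <- effect_design(seed = 24)
  co <- simulate_cohort(d)
  rep_full <- reproduce_report(co)
  expect_true(all(rep_full$availability$available))
  z1 <- rep_full$summaries
  z1 <- z1[z1$group == "all" & z1$region == "Z1" & z1$eye == "OD", ]
  se <- d$slice_cv[1] * d$slice_means_mm3[1] / sqrt(z1$count)
  expect_lt(abs(z1$mean - d$slice_means_mm3[1]), 3 * se)

  no_meta <- co[setdiff(names(co), c("sex", "origin"))]
  rep_deg <- reproduce_report(no_meta)
  av <- rep_deg$availability
  expect_false(av$available[av$section == "manova"])
  expect_false(av$available[av$section == "anova"])
  expect_true(av$available[av$section == "summaries"])
  expect_false(is.null(rep_deg$summaries))

  tiny <- reproduce_report(co[1:4, ])
  expect_false(tiny$availability$available[tiny$availability$section == "pca"])
})

test_that("tidiers return the documented shapes", {
  co <- make_cohort(n_animals = 60, seed = 25)
  p <- pca_slices(co, "OS")
  expect_equal(nrow(tidy(p)), 9)
  expect_equal(glance(p)$cumvar_pc3, p$cumulative_fraction[3])
  m <- manova_slices(co, "OS")
  expect_true(all(c("term", "wilks", "p.value") %in% names(tidy(m))))
  a <- anova_per_slice(co, "OS")
  expect_true(all(c("slice", "term", "stars") %in% names(tidy(a))))
  expect_s3_class(autoplot(p), "ggplot")
  expect_s3_class(plot_cohort_volumes(co, "slices"), "ggplot")
})
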