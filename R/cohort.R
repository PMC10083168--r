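#' Design of a simulated reference cohort
#'
#' Describes a cohort of animals contributing per-eye 9-slice volume vectors
#' drawn from a multivariate normal with configurable means, coefficients of
#' variation and between-slice correlation, plus additive sex and origin
#' effects. Defaults reproduce the normative study conditions: 187 animals x
#' 2 eyes = 374 eyes, 39.3% female eyes, 4.3% of animals of unknown origin
#' and 55.6% of the rest Mauritian, slice means and CVs at the normative
#' right-eye table values (central slice 0.205 mm^3, CV 7.9%), and a uniform
#' between-slice correlation of 0.5 (the observed mean among-slice
#' correlation is 0.49).
#'
#' Fellow eyes of one animal share an animal-level random intercept with
#' intraclass correlation `icc` (the marginal per-eye covariance is
#' unchanged); downstream analyses treat eyes as independent, matching the
#' reference analysis.
#'
#' @param n_animals Number of animals.
#' @param eyes_per_animal 1 or 2 eyes per animal.
#' @param p_female Probability an animal is female.
#' @param p_mauritius Probability a known-origin animal is Mauritian.
#' @param p_unknown_origin Probability an animal's origin is unknown.
#' @param slice_means_mm3 Length-9 baseline slice volumes (mm^3).
#' @param slice_cv Length-9 coefficients of variation.
#' @param between_slice_corr 9x9 correlation matrix (default uniform 0.5
#'   off-diagonal).
#' @param sex_effect_mm3 Length-9 additive female-minus-male offsets.
#' @param origin_effect_mm3 Length-9 additive Mauritius-minus-Asia offsets.
#' @param icc Animal-level intraclass correlation between fellow eyes.
#' @param seed Random seed.
#' @return An object of class `effect_design`.
#' @export
effect_design <- function(n_animals = 187, eyes_per_animal = 2,
                          p_female = 147 / 374,
                          p_mauritius = 199 / 358,
                          p_unknown_origin = 16 / 374,
                          slice_means_mm3 = c(0.205, 0.191, 0.199, 0.188, 0.191,
                                              0.351, 0.347, 0.352, 0.325),
                          slice_cv = c(0.079, 0.061, 0.048, 0.063, 0.045,
                                       0.054, 0.039, 0.055, 0.038),
                          between_slice_corr = NULL,
                          sex_effect_mm3 = rep(0, 9),
                          origin_effect_mm3 = rep(0, 9),
                          icc = 0.8, seed = 1L) {
  if (is.null(between_slice_corr)) {
    between_slice_corr <- matrix(0.5, 9, 9); diag(between_slice_corr) <- 1
  }
  stopifnot(length(slice_means_mm3) == 9, length(slice_cv) == 9,
            length(sex_effect_mm3) == 9, length(origin_effect_mm3) == 9,
            identical(dim(between_slice_corr), c(9L, 9L)),
            eyes_per_animal %in% 1:2)
  probs <- c(p_female, p_mauritius, p_unknown_origin)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (max(abs(between_slice_corr - t(between_slice_corr))) > 1e-12 ||
      any(abs(diag(between_slice_corr) - 1) > 1e-12)) {
    stop("between_slice_corr must be symmetric with unit diagonal", call. = FALSE)
  }
  if (min(eigen(between_slice_corr, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-10) {
    stop("between_slice_corr is not positive semi-definite", call. = FALSE)
  }
  structure(
    list(n_animals = as.integer(n_animals), eyes_per_animal = as.integer(eyes_per_animal),
         p_female = p_female, p_mauritius = p_mauritius,
         p_unknown_origin = p_unknown_origin,
         slice_means_mm3 = slice_means_mm3, slice_cv = slice_cv,
         between_slice_corr = between_slice_corr,
         sex_effect_mm3 = sex_effect_mm3, origin_effect_mm3 = origin_effect_mm3,
         icc = icc, seed = as.integer(seed)),
    class = "effect_design"
  )
}

# Marginal per-eye covariance of the nine slice volumes implied by a design.
design_sigma <- function(design) {
  sdv <- design$slice_cv * design$slice_means_mm3
  diag(sdv) %*% design$between_slice_corr %*% diag(sdv)
}

# Linear map from the 9 slices to the 16 canonical regions
# (Z1-Z3, Q1-Q4, S1-S9), used both to derive regions in simulation and as
# an analytic oracle for region-level covariance.
region_composition_matrix <- function(grid = grid_spec()) {
  A <- matrix(0, 16, 9, dimnames = list(region_ids(), slice_ids()))
  A["Z1", "S1"] <- 1
  A["Z2", paste0("S", 2:5)] <- 1
  A["Z3", paste0("S", 6:9)] <- 1
  for (k in seq_along(grid$sector_slices)) {
    sl <- grid$sector_slices[[k]]
    A[paste0("Q", k), "S1"] <- 1 / 4
    A[paste0("Q", k), paste0("S", sl[["inner"]])] <- 1
    A[paste0("Q", k), paste0("S", sl[["outer"]])] <- 1
  }
  for (s in 1:9) A[paste0("S", s), paste0("S", s)] <- 1
  A
}

#' Simulate a per-eye reference cohort
#'
#' Draws one record per eye: animal metadata (sex, origin, eye side, age,
#' weight) and a 9-slice volume vector from the design's multivariate
#' normal, with additive group effects and an animal-level random intercept
#' shared by fellow eyes. Zones and quadrants are derived from the slices by
#' the grid composition rule. Deterministic given the design's seed.
#'
#' @param design An [effect_design()].
#' @param grid A [grid_spec()] (supplies the quadrant composition).
#' @return A cohort tibble: `animal_id`, `eye`, `sex`, `origin`,
#'   `age_months`, `weight_kg`, `Z1`-`Z3`, `Q1`-`Q4`, `S1`-`S9` (mm^3).
#' @export
simulate_cohort <- function(design = effect_design(), grid = grid_spec()) {
  stopifnot(inherits(design, "effect_design"))
  sigma <- design_sigma(design)
  ee <- eigen(sigma, symmetric = TRUE)
  if (min(ee$values) < -1e-10 * max(abs(ee$values), 1)) {
    stop("slice covariance is not positive semi-definite", call. = FALSE)
  }
  # PSD square root: exact for singular covariances (zero CVs stay constants)
  L <- diag(sqrt(pmax(ee$values, 0)), 9) %*% t(ee$vectors)
  n <- design$n_animals
  k <- design$eyes_per_animal
  with_local_seed(design$seed, {
    sex <- ifelse(stats::runif(n) < design$p_female, "female", "male")
    origin <- ifelse(stats::runif(n) < design$p_unknown_origin, "unknown",
                     ifelse(stats::runif(n) < design$p_mauritius, "Mauritius", "Asia"))
    age <- round(stats::runif(n, 30, 50))
    weight <- round(stats::runif(n, 2.5, 5.5), 1)
    a <- matrix(stats::rnorm(n * 9), n, 9) %*% L * sqrt(design$icc)

    idx <- rep(seq_len(n), each = k)
    eyes <- if (k == 2) rep(c("OD", "OS"), n) else
      sample(c("OD", "OS"), n, replace = TRUE)
    mu <- matrix(design$slice_means_mm3, n, 9, byrow = TRUE) +
      outer(sex == "female", design$sex_effect_mm3) +
      outer(origin == "Mauritius", design$origin_effect_mm3)
    e <- matrix(stats::rnorm(n * k * 9), n * k, 9) %*% L * sqrt(1 - design$icc)
    S <- mu[idx, , drop = FALSE] + a[idx, , drop = FALSE] + e
    colnames(S) <- slice_ids()

    A <- region_composition_matrix(grid)
    reg <- S %*% t(A)
    dplyr::bind_cols(
      tibble::tibble(animal_id = sprintf("A%04d", idx), eye = eyes,
                     sex = sex[idx], origin = origin[idx],
                     age_months = age[idx], weight_kg = weight[idx]),
      tibble::as_tibble(reg[, region_ids(), drop = FALSE]))
  })
}
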