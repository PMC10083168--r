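#' Grouped summary statistics of a regional volume
#'
#' Count, mean, sample standard deviation (n-1 denominator), minimum, median,
#' maximum and coefficient of variation (std/mean) of one regional volume,
#' optionally grouped by eye side, sex and/or origin. Empty groups are simply
#' absent from the output.
#'
#' @param cohort Cohort tibble (see [simulate_cohort()] /
#'   [read_cohort_table()]).
#' @param region Region column to summarise (`"Z1"`..`"S9"`).
#' @param group_keys Character subset of `c("eye", "sex", "origin")`, or NULL
#'   for an overall summary.
#' @return Tibble with grouping columns and `count`, `mean`, `std`, `min`,
#'   `median`, `max`, `cv`.
#' @export
summarize_volumes <- function(cohort, region = "Z1", group_keys = NULL) {
  stopifnot(region %in% region_ids(), region %in% names(cohort))
  if (!is.null(group_keys)) {
    stopifnot(all(group_keys %in% c("eye", "sex", "origin")))
  }
  v <- rlang::sym(region)
  cohort |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_keys))) |>
    dplyr::summarise(
      region = region,
      count = dplyr::n(),
      mean = mean(!!v),
      std = stats::sd(!!v),
      min = min(!!v),
      median = stats::median(!!v),
      max = max(!!v),
      cv = ifelse(mean(!!v) > 0, stats::sd(!!v) / mean(!!v), NA_real_),
      .groups = "drop"
    )
}

# pair blocks of the 16-region correlation matrix
correlation_blocks <- function() {
  z <- paste0("Z", 1:3); q <- paste0("Q", 1:4); s <- paste0("S", 1:9)
  list(among_zones = list(z, z), among_quadrants = list(q, q),
       among_slices = list(s, s), zones_x_quadrants = list(z, q),
       zones_x_slices = list(z, s), quadrants_x_slices = list(q, s))
}

#' Pearson correlation block summaries
#'
#' Computes all pairwise Pearson correlations within and between the three
#' region families (zones Z1-Z3, quadrants Q1-Q4, slices S1-S9) and
#' summarises each block (mean, min, quartiles, max). All eyes are pooled by
#' default. Pairs involving a zero-variance region are undefined; they are
#' excluded from the summaries and counted in `n_excluded`.
#'
#' @param cohort Cohort tibble.
#' @param eye_side `"both"` (pooled, default), `"OD"` or `"OS"`.
#' @return Tibble with one row per block: `block`, `n_pairs`, `n_excluded`,
#'   `mean`, `min`, `q25`, `q50`, `q75`, `max`.
#' @export
correlation_block_summary <- function(cohort, eye_side = c("both", "OD", "OS")) {
  eye_side <- match.arg(eye_side)
  if (eye_side != "both") cohort <- dplyr::filter(cohort, .data$eye == eye_side)
  if (nrow(cohort) < 3) stop("need at least 3 records for correlations", call. = FALSE)
  X <- as.matrix(cohort[region_ids()])
  # near-zero variance counts as degenerate: nominally constant columns can
  # carry ~1e-10 relative jitter from the simulator's covariance square root,
  # and correlations at that scale are numerically meaningless
  sds <- apply(X, 2, stats::sd)
  ok <- sds > 1e-8 * pmax(abs(colMeans(X)), 1e-300)
  R <- matrix(NA_real_, 16, 16, dimnames = list(region_ids(), region_ids()))
  if (any(ok)) R[ok, ok] <- stats::cor(X[, ok, drop = FALSE])
  purrr::imap_dfr(correlation_blocks(), function(fam, nm) {
    a <- fam[[1]]; b <- fam[[2]]
    if (identical(a, b)) {
      idx <- which(upper.tri(R[a, b]), arr.ind = TRUE)
      vals <- R[a, b][upper.tri(R[a, b])]
    } else {
      vals <- as.vector(R[a, b])
    }
    defined <- vals[!is.na(vals)]
    qs <- if (length(defined)) stats::quantile(defined, c(.25, .5, .75)) else rep(NA_real_, 3)
    tibble::tibble(block = nm, n_pairs = length(vals),
                   n_excluded = sum(is.na(vals)),
                   mean = if (length(defined)) mean(defined) else NA_real_,
                   min = if (length(defined)) min(defined) else NA_real_,
                   q25 = qs[[1]], q50 = qs[[2]], q75 = qs[[3]],
                   max = if (length(defined)) max(defined) else NA_real_)
  })
}

#' Principal component analysis of the slice volumes
#'
#' Eigendecomposition of the sample covariance matrix of S1-S9 for one eye
#' side. The covariance (not correlation) matrix is used because all nine
#' variables share mm^3 units. Eigenvalues are returned in descending order;
#' each eigenvector's sign is fixed so that its largest-magnitude entry is
#' positive.
#'
#' @param cohort Cohort tibble.
#' @param eye_side `"OD"` or `"OS"`.
#' @return A `retvol_pca`: `eigenvalues`, `explained_fraction`,
#'   `cumulative_fraction` (length-9), `coefficients` (9x9, columns =
#'   components), `eye_side`, `n`.
#' @export
pca_slices <- function(cohort, eye_side = c("OD", "OS")) {
  eye_side <- match.arg(eye_side)
  X <- as.matrix(dplyr::filter(cohort, .data$eye == eye_side)[slice_ids()])
  if (nrow(X) < 10) {
    stop(sprintf("need >= 10 %s records for PCA, have %d", eye_side, nrow(X)),
         call. = FALSE)
  }
  ee <- eigen(stats::cov(X), symmetric = TRUE)
  V <- ee$vectors
  for (j in seq_len(ncol(V))) {
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  }
  dimnames(V) <- list(slice_ids(), paste0("PC", 1:9))
  lam <- pmax(ee$values, 0)
  structure(list(eigenvalues = lam,
                 explained_fraction = lam / sum(lam),
                 cumulative_fraction = cumsum(lam) / sum(lam),
                 coefficients = V, eye_side = eye_side, n = nrow(X)),
            class = "retvol_pca")
}

#' @export
print.retvol_pca <- function(x, ...) {
  cat(sprintf("<retvol_pca> %s eyes, n = %d; first 3 PCs explain %.1f%%\n",
              x$eye_side, x$n, 100 * x$cumulative_fraction[3]))
  invisible(x)
}

# --- shared two-factor linear-model machinery -------------------------------

# Filter one eye side, drop unknown-origin records, check factor levels.
stats_frame <- function(cohort, eye_side) {
  d <- cohort |>
    dplyr::filter(.data$eye == eye_side, .data$origin != "unknown") |>
    dplyr::mutate(sex = factor(.data$sex, levels = c("male", "female")),
                  origin = factor(.data$origin, levels = c("Asia", "Mauritius"))) |>
    tidyr::drop_na(dplyr::all_of(c("sex", "origin", slice_ids())))
  for (f in c("sex", "origin")) {
    if (length(unique(d[[f]])) < 2) {
      stop(sprintf("factor '%s' has a single level after exclusions", f),
           call. = FALSE)
    }
  }
  d
}

# QR decompositions of the four candidate model matrices.
design_qrs <- function(d) {
  list(int  = qr(stats::model.matrix(~ sex * origin, d)),
       add  = qr(stats::model.matrix(~ sex + origin, d)),
       sex  = qr(stats::model.matrix(~ sex, d)),
       orig = qr(stats::model.matrix(~ origin, d)))
}

# Wilks' lambda -> Rao's F approximation (exact when hypothesis df q = 1).
wilks_to_f <- function(lambda, p, q, v) {
  t <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  w <- v + q - (p + q + 1) / 2
  df1 <- p * q
  df2 <- w * t - (p * q - 2) / 2
  lam_t <- lambda^(1 / t)
  f <- (1 - lam_t) / lam_t * df2 / df1
  list(F = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Two-factor MANOVA of the slice volumes (Wilks' lambda)
#'
#' Multivariate linear model of S1-S9 on sex and origin for one eye side,
#' with unknown-origin records excluded. The model is first fitted with the
#' sex:origin interaction; if the interaction's Wilks test has
#' p >= `drop_interaction_at` it is removed and the additive model is
#' refitted. Per-factor tests are type II: the hypothesis SSCP of each
#' factor is its increment over the model containing the other factor.
#' Wilks' lambda is converted to an F statistic by Rao's approximation
#' (exact here, where each factor has one degree of freedom).
#'
#' @param cohort Cohort tibble.
#' @param eye_side `"OD"` or `"OS"`.
#' @param drop_interaction_at Significance level at which the interaction is
#'   retained (kept only if its p-value is below this).
#' @return A `retvol_manova`: tibble of per-term results plus the
#'   interaction decision.
#' @export
manova_slices <- function(cohort, eye_side = c("OD", "OS"),
                          drop_interaction_at = 0.01) {
  eye_side <- match.arg(eye_side)
  d <- stats_frame(cohort, eye_side)
  Y <- as.matrix(d[slice_ids()])
  n <- nrow(Y); p <- ncol(Y)
  qrs <- design_qrs(d)
  E_int <- crossprod(qr.resid(qrs$int, Y))
  E_add <- crossprod(qr.resid(qrs$add, Y))

  wilks_term <- function(E, H, v) {
    lambda <- det(E) / det(E + H)
    c(list(wilks = lambda), wilks_to_f(lambda, p, 1, v))
  }
  int_test <- wilks_term(E_int, E_add - E_int, n - 4)
  keep_int <- int_test$p < drop_interaction_at

  if (keep_int) {
    E <- E_int; v <- n - 4
  } else {
    E <- E_add; v <- n - 3
  }
  sex_t <- wilks_term(E, crossprod(qr.resid(qrs$orig, Y)) - E_add, v)
  ori_t <- wilks_term(E, crossprod(qr.resid(qrs$sex, Y)) - E_add, v)

  rows <- list(sex = sex_t, origin = ori_t)
  if (keep_int) rows$`sex:origin` <- int_test
  tab <- purrr::imap_dfr(rows, function(r, nm) {
    tibble::tibble(term = nm, wilks = r$wilks, statistic = r$F,
                   df1 = r$df1, df2 = r$df2, p.value = r$p)
  })
  structure(list(table = tab, interaction_p = int_test$p,
                 interaction_dropped = !keep_int,
                 eye_side = eye_side, n = n),
            class = "retvol_manova")
}

#' @export
print.retvol_manova <- function(x, ...) {
  cat(sprintf("<retvol_manova> %s eyes, n = %d (interaction %s, p = %.3g)\n",
              x$eye_side, x$n,
              if (x$interaction_dropped) "dropped" else "kept", x$interaction_p))
  print(x$table)
  invisible(x)
}

#' Per-slice two-factor ANOVA with Bonferroni stars
#'
#' For each slice S1-S9, a univariate linear model on sex and origin (one
#' eye side, unknown-origin records excluded) with type II sums of squares
#' on the unbalanced design. Per slice, the sex:origin interaction is kept
#' only if its F-test has p below `drop_interaction_at`; otherwise the
#' additive model supplies the error term. Significance stars apply the
#' Bonferroni correction for the nine slice tests: `***` p < 0.001/9,
#' `**` p < 0.01/9, `*` p < 0.05/9 (see [bonferroni_stars()]).
#'
#' @param cohort Cohort tibble.
#' @param eye_side `"OD"` or `"OS"`.
#' @param drop_interaction_at Level at which interactions are retained
#'   (default 0.01/9, the Bonferroni-corrected 1% level).
#' @param m Number of tests in the Bonferroni correction.
#' @return A `retvol_anova`: tibble with `slice`, `term`, `statistic` (F),
#'   `df1`, `df2`, `p.value`, `stars`, plus the per-slice interaction
#'   decisions.
#' @export
anova_per_slice <- function(cohort, eye_side = c("OD", "OS"),
                            drop_interaction_at = 0.01 / 9, m = 9) {
  eye_side <- match.arg(eye_side)
  d <- stats_frame(cohort, eye_side)
  Y <- as.matrix(d[slice_ids()])
  n <- nrow(Y)
  qrs <- design_qrs(d)
  rss <- lapply(qrs, function(q) colSums(qr.resid(q, Y)^2))

  out <- vector("list", 9)
  int_p <- numeric(9)
  for (s in 1:9) {
    f_int <- (rss$add[s] - rss$int[s]) / (rss$int[s] / (n - 4))
    p_int <- stats::pf(f_int, 1, n - 4, lower.tail = FALSE)
    int_p[s] <- p_int
    keep_int <- p_int < drop_interaction_at
    err_ss <- if (keep_int) rss$int[s] else rss$add[s]
    err_df <- if (keep_int) n - 4 else n - 3
    ss_sex <- rss$orig[s] - rss$add[s]
    ss_ori <- rss$sex[s] - rss$add[s]
    terms <- tibble::tibble(
      slice = slice_ids()[s],
      term = c("sex", "origin", if (keep_int) "sex:origin"),
      statistic = unname(c(ss_sex, ss_ori, if (keep_int) rss$add[s] - rss$int[s]) /
                           (err_ss / err_df)),
      df1 = 1, df2 = err_df)
    terms$p.value <- stats::pf(terms$statistic, terms$df1, terms$df2,
                               lower.tail = FALSE)
    terms$stars <- bonferroni_stars(terms$p.value, m = m)
    out[[s]] <- terms
  }
  structure(list(table = dplyr::bind_rows(out),
                 interaction_p = stats::setNames(int_p, slice_ids()),
                 drop_interaction_at = drop_interaction_at,
                 eye_side = eye_side, n = n, m = m),
            class = "retvol_anova")
}

#' @export
print.retvol_anova <- function(x, ...) {
  cat(sprintf("<retvol_anova> %s eyes, n = %d, Bonferroni m = %d\n",
              x$eye_side, x$n, x$m))
  print(x$table)
  invisible(x)
}

#' Bonferroni significance stars
#'
#' Star string for a p-value under Bonferroni correction for `m` tests:
#' `"***"` if p < 0.001/m, `"**"` if p < 0.01/m, `"*"` if p < 0.05/m,
#' `""` otherwise. Inequalities are strict.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @param m Number of tests.
#' @return Character vector of stars.
#' @examples
#' bonferroni_stars(c(9.8e-6, 3.0e-3, 0.05 / 9))
#' @export
bonferroni_stars <- function(p, m = 9) {
  stopifnot(m >= 1, all(p >= 0 & p <= 1, na.rm = TRUE))
  dplyr::case_when(
    p < 0.001 / m ~ "***",
    p < 0.01 / m ~ "**",
    p < 0.05 / m ~ "*",
    TRUE ~ ""
  )
}

#' Full reference-database report
#'
#' Machine-readable analogue of the normative study's result tables:
#' grouped summaries of zones, quadrants and slices (by eye side and
#' sex/origin subgroup, plus overall per side), the correlation block
#' summary, per-side PCA of the slices, per-side MANOVA and per-slice
#' ANOVA. Sections whose requirements are not met (missing metadata,
#' insufficient records) are marked unavailable rather than aborting the
#' report.
#'
#' @param cohort Cohort tibble.
#' @return A `retvol_report`: named list of sections plus an `availability`
#'   tibble.
#' @export
reproduce_report <- function(cohort) {
  avail <- list()
  section <- function(name, expr) {
    avail[[name]] <<- NA_character_
    tryCatch(expr, error = function(e) {
      avail[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  has_meta <- all(c("sex", "origin") %in% names(cohort))

  summaries <- section("summaries", {
    keys <- if (has_meta) c("eye", "sex", "origin") else "eye"
    grouped <- purrr::map_dfr(region_ids(),
                              ~ summarize_volumes(cohort, .x, group_keys = keys))
    overall <- purrr::map_dfr(region_ids(),
                              ~ summarize_volumes(cohort, .x, group_keys = "eye"))
    dplyr::bind_rows(dplyr::mutate(overall, group = "all"),
                     dplyr::mutate(grouped, group = "by_sex_origin"))
  })
  correlation <- section("correlation", correlation_block_summary(cohort))
  pca <- section("pca", lapply(stats::setNames(c("OD", "OS"), c("OD", "OS")),
                               function(e) pca_slices(cohort, e)))
  manova <- if (has_meta) {
    section("manova", lapply(stats::setNames(c("OD", "OS"), c("OD", "OS")),
                             function(e) manova_slices(cohort, e)))
  } else {
    avail$manova <- "sex/origin metadata missing"
    NULL
  }
  anova <- if (has_meta) {
    section("anova", lapply(stats::setNames(c("OD", "OS"), c("OD", "OS")),
                            function(e) anova_per_slice(cohort, e)))
  } else {
    avail$anova <- "sex/origin metadata missing"
    NULL
  }

  availability <- tibble::tibble(
    section = names(avail),
    available = is.na(unlist(avail)),
    reason = unlist(avail)
  )
  structure(list(summaries = summaries, correlation = correlation, pca = pca,
                 manova = manova, anova = anova, availability = availability),
            class = "retvol_report")
}

#' @export
print.retvol_report <- function(x, ...) {
  cat("<retvol_report>\n")
  print(x$availability)
  invisible(x)
}
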