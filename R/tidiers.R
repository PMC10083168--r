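#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a slice-volume PCA
#'
#' @param x A `retvol_pca`.
#' @param ... Unused.
#' @return One row per component: `component`, `eigenvalue`,
#'   `explained_fraction`, `cumulative_fraction`.
#' @export
tidy.retvol_pca <- function(x, ...) {
  tibble::tibble(component = paste0("PC", 1:9),
                 eigenvalue = x$eigenvalues,
                 explained_fraction = x$explained_fraction,
                 cumulative_fraction = x$cumulative_fraction)
}

#' @rdname tidy.retvol_pca
#' @return `glance()`: one row with `eye_side`, `n`, `cumvar_pc3`.
#' @export
glance.retvol_pca <- function(x, ...) {
  tibble::tibble(eye_side = x$eye_side, n = x$n,
                 cumvar_pc3 = x$cumulative_fraction[3])
}

#' Tidy MANOVA results
#'
#' @param x A `retvol_manova`.
#' @param ... Unused.
#' @return Per-term tibble: `term`, `wilks`, `statistic`, `df1`, `df2`,
#'   `p.value`.
#' @export
tidy.retvol_manova <- function(x, ...) x$table

#' @rdname tidy.retvol_manova
#' @export
glance.retvol_manova <- function(x, ...) {
  tibble::tibble(eye_side = x$eye_side, n = x$n,
                 interaction_p = x$interaction_p,
                 interaction_dropped = x$interaction_dropped)
}

#' Tidy per-slice ANOVA results
#'
#' @param x A `retvol_anova`.
#' @param ... Unused.
#' @return Per slice x term tibble with F statistics, p-values and
#'   Bonferroni stars.
#' @export
tidy.retvol_anova <- function(x, ...) x$table

#' @rdname tidy.retvol_anova
#' @export
glance.retvol_anova <- function(x, ...) {
  tibble::tibble(eye_side = x$eye_side, n = x$n, m = x$m,
                 n_starred = sum(x$table$stars != ""))
}
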