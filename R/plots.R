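#' Scree plot of a slice-volume PCA
#'
#' Cumulative explained variance of the nine principal components.
#'
#' @param object A `retvol_pca`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.retvol_pca <- function(object, ...) {
  d <- tidy(object)
  d$component <- factor(d$component, levels = d$component)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component,
                                  y = .data$cumulative_fraction, group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x),
                                limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "cumulative explained variance",
                  title = sprintf("PCA of slice volumes, %s eyes (n = %d)",
                                  object$eye_side, object$n)) +
    ggplot2::theme_minimal()
}

#' Grouped boxplots of regional volumes
#'
#' Distribution of one region family (zones, quadrants or slices) by
#' sex/origin subgroup, faceted by eye side.
#'
#' @param cohort Cohort tibble.
#' @param family `"zones"`, `"quadrants"` or `"slices"`.
#' @return A ggplot.
#' @export
plot_cohort_volumes <- function(cohort, family = c("zones", "quadrants", "slices")) {
  family <- match.arg(family)
  cols <- switch(family, zones = paste0("Z", 1:3), quadrants = paste0("Q", 1:4),
                 slices = paste0("S", 1:9))
  d <- cohort |>
    dplyr::filter(.data$origin != "unknown") |>
    tidyr::pivot_longer(dplyr::all_of(cols), names_to = "region",
                        values_to = "volume_mm3") |>
    dplyr::mutate(group = paste(substr(.data$sex, 1, 1),
                                substr(.data$origin, 1, 1), sep = "/"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$region, y = .data$volume_mm3,
                                  fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_wrap(~eye) +
    ggplot2::labs(y = expression(volume ~ (mm^3)), x = NULL, fill = "sex/origin") +
    ggplot2::theme_minimal()
}

#' En-face raster of the region masks
#'
#' Visual inspection aid: each A-scan column colored by its slice
#' assignment, with the nulla marked.
#'
#' @param masks A [build_region_masks()] result.
#' @return A ggplot.
#' @export
plot_region_masks <- function(masks) {
  stopifnot(inherits(masks, "region_masks"))
  g <- masks$geometry
  d <- expand.grid(b = seq_len(g$n_bscans), x = seq_len(g$ascans_per_bscan))
  d$slice <- as.vector(masks$slice)
  d$x_mm <- ascan_x_mm(d$x, g)
  d$y_mm <- bscan_y_mm(d$b, g)
  d$slice <- factor(ifelse(d$slice == 0, "outside", paste0("S", d$slice)),
                    levels = c(paste0("S", 1:9), "outside"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x_mm, y = .data$y_mm,
                                  fill = .data$slice)) +
    ggplot2::geom_tile() +
    ggplot2::annotate("point", x = masks$nulla$x_mm, y = masks$nulla$y_mm,
                      shape = 3, size = 3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = NULL,
                  title = sprintf("%s, clipped fraction %.3f", masks$eye,
                                  masks$clipped_fraction)) +
    ggplot2::theme_minimal()
}
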