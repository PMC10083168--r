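#' Default tissue-class rendering/segmentation intensities
#'
#' Mean grayscale intensity (0-255) per tissue class, shared by the phantom
#' renderer and the rule-based segmenter. Values are spread so that adjacent
#' classes in intensity are at least 60 gray levels apart.
#'
#' @return Named numeric vector (vitreous, retina, choroid, sclera).
#' @export
default_class_intensities <- function() {
  c(vitreous = 20, retina = 150, choroid = 80, sclera = 210)
}

#' Segment one B-scan into tissue labels
#'
#' Deterministic rule-based semantic segmentation with the same output
#' contract as a learned pixel-wise segmenter: every pixel receives one of
#' the labels vitreous/retina/choroid/sclera. Pixels are first assigned to
#' the nearest class mean intensity (i.e. thresholds at class-mean
#' midpoints); then a per-column cleanup keeps the largest contiguous run of
#' each class and rebuilds the column as the anatomically ordered stack
#' vitreous -> retina -> choroid -> sclera from the run boundaries. Columns
#' whose class runs cannot be ordered (or that contain no retina) are
#' flagged but still labelled.
#'
#' @param image Numeric matrix (axial rows x A-scan columns), 0-255 scale.
#' @param class_intensities Named mean intensity per class.
#' @return Integer label matrix with attribute `flagged_columns` (indices of
#'   columns without a usable retina run or with unordered runs).
#' @export
segment_bscan <- function(image, class_intensities = default_class_intensities()) {
  stopifnot(is.matrix(image))
  ord <- order(class_intensities)
  cuts <- (class_intensities[ord][-1] + class_intensities[ord][-4]) / 2
  nearest <- ord[findInterval(image, cuts) + 1L]   # class index 1..4 per pixel
  raw <- matrix(as.integer(nearest), nrow(image), ncol(image))
  # axial median-3 denoise: isolated single-pixel flips would otherwise split
  # a class's largest run and drag the rebuilt boundary by many pixels
  raw <- column_median3(raw)

  nz <- nrow(raw)
  out <- raw
  flagged <- integer(0)
  for (j in seq_len(ncol(raw))) {
    col <- raw[, j]
    starts <- run_starts_per_class(col, nz)
    # boundary rows: first row of the largest retina/choroid/sclera run
    b <- c(starts["retina"], starts["choroid"], starts["sclera"])
    if (is.na(b[1])) {
      out[, j] <- tissue_labels()[["vitreous"]]
      flagged <- c(flagged, j)
      next
    }
    if (any(diff(b[!is.na(b)]) <= 0)) flagged <- c(flagged, j)
    b[is.na(b)] <- nz + 1L
    b <- cummax(b)                                  # enforce anatomical order
    z <- seq_len(nz)
    out[, j] <- 1L + (z >= b[1]) + (z >= b[2]) + (z >= b[3])
  }
  attr(out, "flagged_columns") <- flagged
  out
}

# Per-column median of each pixel with its axial neighbours (edge rows keep
# their value); labels are ordinal along the column so the median is defined.
column_median3 <- function(m) {
  nz <- nrow(m)
  up <- m[c(1L, seq_len(nz - 1L)), , drop = FALSE]
  dn <- m[c(seq_len(nz - 1L) + 1L, nz), , drop = FALSE]
  m + up + dn - pmax(m, up, dn) - pmin(m, up, dn)
}

# First row of the largest contiguous run of each class in a label column.
run_starts_per_class <- function(col, nz) {
  r <- rle(col)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  res <- c(retina = NA_integer_, choroid = NA_integer_, sclera = NA_integer_)
  lab <- tissue_labels()
  for (cls in names(res)) {
    k <- which(r$values == lab[[cls]])
    if (length(k)) {
      best <- k[which.max(r$lengths[k])]
      res[cls] <- starts[best]
    }
  }
  res
}

#' Segment a full B-scan stack
#'
#' Applies [segment_bscan()] to every image and assembles a `label_volume`.
#'
#' @param stack A `bscan_stack`.
#' @param class_intensities Named mean intensity per class.
#' @return A `label_volume`; per-B-scan flagged columns are stored in the
#'   `flags` element.
#' @export
segment_stack <- function(stack, class_intensities = default_class_intensities()) {
  stopifnot(inherits(stack, "bscan_stack"))
  g <- stack$geometry
  labels <- array(NA_integer_, dim = c(g$axial_px, g$ascans_per_bscan, g$n_bscans))
  flags <- vector("list", g$n_bscans)
  for (ib in seq_along(stack$images)) {
    m <- segment_bscan(stack$images[[ib]], class_intensities)
    labels[, , ib] <- m
    flags[[ib]] <- attr(m, "flagged_columns")
  }
  vol <- new_label_volume(labels, g)
  vol$flags <- flags
  vol
}

#' Validate a label volume
#'
#' Pure QC over any source of labels (rule-based, learned, or ingested):
#' counts per B-scan the columns whose classes are out of anatomical order,
#' the columns with zero retina pixels, and the retina-thickness outliers
#' (columns whose retina pixel count deviates from the volume-wide mean by
#' more than `z_threshold` standard deviations).
#'
#' @param volume A `label_volume`.
#' @param z_threshold Outlier z-score threshold on per-column retina
#'   thickness.
#' @return Tibble with one row per B-scan: `bscan`, `n_out_of_order`,
#'   `n_zero_retina`, `n_thickness_outliers`.
#' @export
validate_label_volume <- function(volume, z_threshold = 6) {
  stopifnot(inherits(volume, "label_volume"))
  lab <- tissue_labels()
  d <- dim(volume$labels)
  ret_count <- apply(volume$labels == lab[["retina"]], c(2, 3), sum)  # [x, b]
  mu <- mean(ret_count); sdv <- stats::sd(as.vector(ret_count))
  per_b <- lapply(seq_len(d[3]), function(ib) {
    sl <- volume$labels[, , ib]
    ooo <- sum(vapply(seq_len(d[2]), function(j) {
      is.unsorted(sl[, j], strictly = FALSE)
    }, logical(1)))
    zr <- sum(ret_count[, ib] == 0)
    outl <- if (sdv > 0) sum(abs(ret_count[, ib] - mu) / sdv > z_threshold) else 0L
    tibble::tibble(bscan = ib, n_out_of_order = ooo, n_zero_retina = zr,
                   n_thickness_outliers = outl)
  })
  dplyr::bind_rows(per_b)
}
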