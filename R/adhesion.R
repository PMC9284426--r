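#' Select the in-focus plane of a stack by normalized variance
#'
#' The focal-adhesion plane (the ventral, substrate-contacting surface) is
#' identified as the optical slice with the largest normalized variance
#' (variance / mean, the standard autofocus metric). Ties resolve to the
#' lowest slice index; a slice with zero mean has normalized variance 0,
#' and an all-zero stack is flagged and returns slice 1.
#'
#' @param stack A `volume_stack` or 3D array.
#' @param channel Channel to evaluate.
#' @return List with `plane` (1-based z index), `metric` (per-slice
#'   normalized variance), `flags`.
#' @export
select_focus_plane <- function(stack, channel = "adhesion") {
  a <- .stack_channel(stack, channel)
  nz <- dim(a)[3]
  metric <- vapply(seq_len(nz), function(z) {
    s <- a[, , z]
    m <- mean(s)
    if (m <= 0) 0 else stats::var(as.numeric(s)) / m
  }, numeric(1))
  if (all(metric == 0)) {
    return(list(plane = 1L, metric = metric, flags = "no_signal"))
  }
  list(plane = which.max(metric), metric = metric, flags = "")
}

#' Segment focal adhesions on a focused projection
#'
#' Maximum projection of the three confocal slices centered on the focus
#' plane (clamped at stack edges), thresholded (Otsu by default, so the
#' segmentation is invariant to positive intensity scaling), connected
#' components labelled, and specks below `min_size` pixels discarded.
#'
#' @param stack `volume_stack` or 3D array (adhesion marker, e.g. vinculin).
#' @param plane Focus plane (1-based); default from [select_focus_plane()].
#' @param threshold `"otsu"` or a numeric absolute threshold.
#' @param min_size Minimum adhesion area in pixels.
#' @param channel Channel name.
#' @return List with `labels` (2D integer mask) and `projection`.
#' @export
fa_segment <- function(stack, plane = NULL, threshold = "otsu", min_size = 5,
                       channel = "adhesion") {
  a <- .stack_channel(stack, channel)
  nz <- dim(a)[3]
  if (is.null(plane)) plane <- select_focus_plane(stack, channel)$plane
  stopifnot(plane >= 1, plane <= nz)
  zr <- max(1, plane - 1):min(nz, plane + 1)
  proj <- apply(a[, , zr, drop = FALSE], c(1, 2), max)
  if (max(proj) == 0) {
    return(list(labels = matrix(0L, nrow(proj), ncol(proj)), projection = proj))
  }
  th <- if (identical(threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(.norm01(proj))) * max(proj)
  } else as.numeric(threshold)
  mask <- proj > th
  labels <- as.matrix(EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask))))
  list(labels = relabel_filtered(labels, min_size), projection = proj)
}

#' Focal-adhesion statistics normalized per cell
#'
#' Total adhesion area, count, mean size and total adhesion intensity on an
#' image, normalized to the number of cells via the nucleus count. Per-cell
#' fields are NA when there are no nuclei.
#'
#' @param fa_labels 2D adhesion label mask from [fa_segment()].
#' @param nuclei Nucleus label mask (or an integer nucleus count).
#' @param intensity 2D intensity image (e.g. the focused projection).
#' @param pixel_size Optional pixel edge length (micrometres); areas are
#'   reported in square units when given, else pixels.
#' @return A one-row data.frame (`FAResult`): `fa_count`, `total_fa_area`,
#'   `mean_fa_size`, `total_fa_intensity`, `nuclei_count`,
#'   `fa_area_per_cell`, `fa_count_per_cell`, `fa_intensity_per_cell`,
#'   `flags`.
#' @export
fa_stats <- function(fa_labels, nuclei, intensity = NULL, pixel_size = NA_real_) {
  fa_labels <- as.matrix(fa_labels)
  k <- max(fa_labels)
  px_area <- if (is.finite(pixel_size)) pixel_size^2 else 1
  areas <- if (k > 0) tabulate(fa_labels[fa_labels > 0], nbins = k) * px_area else
    numeric(0)
  total_area <- sum(areas)
  total_int <- if (!is.null(intensity) && k > 0) {
    sum(intensity[fa_labels > 0])
  } else if (k == 0) 0 else NA_real_
  n_nuclei <- if (is.matrix(nuclei)) max(nuclei) else as.integer(nuclei)
  per <- function(x) if (n_nuclei > 0) x / n_nuclei else NA_real_
  data.frame(fa_count = k, total_fa_area = total_area,
             mean_fa_size = if (k > 0) mean(areas) else NA_real_,
             total_fa_intensity = total_int, nuclei_count = n_nuclei,
             fa_area_per_cell = per(total_area),
             fa_count_per_cell = per(k),
             fa_intensity_per_cell = per(total_int),
             flags = if (n_nuclei > 0) "" else "no_nuclei",
             stringsAsFactors = FALSE)
}

#' Condition-level focal-adhesion summary with a minimum-cell guard
#'
#' @param fa_results Data.frame of `FAResult` rows (one per image).
#' @param min_cells Minimum total cells per condition (default 50).
#' @return List of condition means plus `n_cells`, `sufficient`, `flags`.
#' @export
condition_fa_summary <- function(fa_results, min_cells = 50) {
  n <- sum(fa_results$nuclei_count)
  if (n < min_cells) {
    return(list(n_cells = n, mean_fa_area_per_cell = NA_real_,
                mean_fa_size = NA_real_, mean_fa_count_per_cell = NA_real_,
                mean_fa_intensity_per_cell = NA_real_,
                sufficient = FALSE, flags = "insufficient_cells"))
  }
  list(n_cells = n,
       mean_fa_area_per_cell = mean(fa_results$fa_area_per_cell, na.rm = TRUE),
       mean_fa_size = mean(fa_results$mean_fa_size, na.rm = TRUE),
       mean_fa_count_per_cell = mean(fa_results$fa_count_per_cell, na.rm = TRUE),
       mean_fa_intensity_per_cell = mean(fa_results$fa_intensity_per_cell,
                                         na.rm = TRUE),
       sufficient = TRUE, flags = "")
}
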