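#' Multichannel 2D field
#'
#' Container for one imaged field: a named list of equally sized 2D
#' intensity matrices (conventional channel names: `nucleus`,
#' `total_marker`, `surface_marker`; structure channels as needed), plus an
#' optional pixel size.
#'
#' @param channels Named list of numeric matrices, all the same dimension,
#'   intensities >= 0.
#' @param pixel_size Optional pixel edge length in micrometres.
#' @return An object of class `channel_field`.
#' @export
channel_field <- function(channels, pixel_size = NA_real_) {
  stopifnot(is.list(channels), length(channels) >= 1, !is.null(names(channels)))
  dims <- lapply(channels, dim)
  if (length(unique(dims)) != 1) stop("all channels must have the same shape")
  if (any(vapply(channels, function(m) any(m < 0), logical(1)))) {
    stop("channel intensities must be >= 0")
  }
  structure(list(channels = channels, pixel_size = pixel_size),
            class = "channel_field")
}

#' Read a multichannel field from TIFF files
#'
#' @param paths Named character vector of per-channel TIFF paths (names are
#'   the channel names).
#' @param pixel_size Optional pixel size in micrometres.
#' @return A `channel_field`.
#' @export
read_channel_field <- function(paths, pixel_size = NA_real_) {
  stopifnot(!is.null(names(paths)))
  channels <- lapply(paths, function(p) {
    img <- EBImage::readImage(p)
    as.matrix(EBImage::imageData(img))
  })
  channel_field(channels, pixel_size = pixel_size)
}

.norm01 <- function(m) {
  mx <- max(m)
  if (mx > 0) m / mx else m
}

#' Segment nuclei in the nucleus channel
#'
#' Gaussian smoothing, Otsu global threshold, hole filling, then a
#' distance-transform watershed to split touching nuclei; objects smaller
#' than `min_size` pixels are discarded and labels relabelled contiguously
#' from 1. An empty image yields zero labels.
#'
#' @param field A `channel_field` with a `nucleus` channel (or a matrix).
#' @param sigma Smoothing sigma in pixels.
#' @param min_size Minimum nucleus area in pixels.
#' @param watershed_tolerance Minimum depth between distance-map maxima for
#'   a split (larger = fewer splits).
#' @return Integer label matrix (0 = background, labels 1..k).
#' @export
segment_nuclei <- function(field, sigma = 2, min_size = 15,
                           watershed_tolerance = 1) {
  m <- if (inherits(field, "channel_field")) field$channels$nucleus else field
  if (is.null(m)) stop("field has no 'nucleus' channel")
  if (max(m) == 0) return(matrix(0L, nrow(m), ncol(m)))
  img <- EBImage::Image(.norm01(m))
  sm <- EBImage::gblur(img, sigma = sigma)
  th <- EBImage::otsu(sm)
  mask <- sm > th
  mask <- EBImage::fillHull(mask)
  dm <- EBImage::distmap(mask)
  labels <- EBImage::watershed(dm, tolerance = watershed_tolerance)
  relabel_filtered(as.matrix(EBImage::imageData(labels)), min_size)
}

# drop objects below min_size and relabel 1..k contiguously
relabel_filtered <- function(lab, min_size) {
  lab <- as.matrix(lab)
  storage.mode(lab) <- "integer"
  if (max(lab) == 0) return(lab)
  sizes <- tabulate(lab, nbins = max(lab))
  keep <- which(sizes >= min_size)
  map <- integer(max(lab))
  map[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0
  out[nz] <- map[lab[nz]]
  out
}

#' Segment cells around nucleus seeds
#'
#' Partitions the stained foreground into one cell territory per nucleus by
#' seeded region growing on the intensity landscape of `channel`
#' (the CellProfiler secondary-object strategy: nuclei are the seeds and
#' region boundaries follow intensity valleys). Each cell contains its seed
#' nucleus; cells partition the foreground.
#'
#' @param field A `channel_field`.
#' @param nuclei Nucleus label matrix from [segment_nuclei()].
#' @param channel Channel on which to grow (default `total_marker`).
#' @param foreground Optional logical matrix; default: Otsu threshold on the
#'   smoothed channel, dilated to cover the nuclei.
#' @param lambda Regularization of the region-growing metric (larger values
#'   approach a pure distance/Voronoi partition).
#' @param merge_seed_distance When > 0, nuclei closer than this many pixels
#'   are merged into a single seed before growing, so multinucleated cells
#'   (e.g. binucleated cells after INCENP knockdown) come out as one cell
#'   containing several nuclei. Default 0: one cell per nucleus.
#' @return Integer label matrix; with the default `merge_seed_distance = 0`
#'   cell label k contains nucleus label k.
#' @export
segment_cells <- function(field, nuclei, channel = "total_marker",
                          foreground = NULL, lambda = 1e-4,
                          merge_seed_distance = 0) {
  m <- field$channels[[channel]]
  if (is.null(m)) stop("field has no '", channel, "' channel")
  nuclei <- as.matrix(nuclei)
  if (max(nuclei) == 0) return(matrix(0L, nrow(m), ncol(m)))
  if (merge_seed_distance > 0) {
    r <- 2L * as.integer(ceiling(merge_seed_distance / 2)) + 1L
    dil <- EBImage::dilate(EBImage::Image(nuclei > 0),
                           EBImage::makeBrush(r, "disc"))
    groups <- as.matrix(EBImage::imageData(EBImage::bwlabel(dil)))
    merged <- matrix(0L, nrow(nuclei), ncol(nuclei))
    merged[nuclei > 0] <- as.integer(groups[nuclei > 0])
    nuclei <- merged
  }
  img <- EBImage::Image(.norm01(m))
  if (is.null(foreground)) {
    sm <- EBImage::gblur(img, sigma = 2)
    th <- EBImage::otsu(sm)
    foreground <- as.matrix(EBImage::imageData(sm)) > th
  }
  foreground <- foreground | nuclei > 0
  cells <- EBImage::propagate(img, seeds = EBImage::Image(nuclei),
                              mask = foreground, lambda = lambda)
  out <- as.matrix(EBImage::imageData(cells))
  storage.mode(out) <- "integer"
  out
}

#' Background-correct a channel
#'
#' Subtracts the image's low-percentile intensity (a flat-background
#' estimate) and clips at zero.
#'
#' @param m Intensity matrix.
#' @param percentile Background percentile (default 0.05).
#' @return Corrected matrix.
#' @export
background_correct <- function(m, percentile = 0.05) {
  pmax(m - stats::quantile(m, percentile, names = FALSE), 0)
}

#' Per-cell transport ratios from a segmented field
#'
#' For each cell, sums the background-corrected surface-marker and
#' total-marker intensities over the cell region and forms the transport
#' ratio surface/total (the per-cell fraction of reporter delivered to the
#' plasma membrane). Cells with non-positive total intensity are flagged
#' (NA ratio) and excluded from downstream spot means. Nucleus counts per
#' cell are attached when a nucleus label mask is given.
#'
#' @param field A `channel_field` with `surface_marker` and `total_marker`.
#' @param cells Cell label matrix.
#' @param nuclei Optional nucleus label matrix for `nucleus_count`.
#' @param bg_percentile Background percentile for [background_correct()];
#'   set NA to skip correction.
#' @return Data.frame of `CellRecord` rows: `cell_id`, `nucleus_count`,
#'   `total_intensity`, `surface_intensity`, `transport_ratio`, `flags`.
#' @export
per_cell_transport_ratio <- function(field, cells, nuclei = NULL,
                                     bg_percentile = 0.05) {
  for (ch in c("surface_marker", "total_marker")) {
    if (is.null(field$channels[[ch]])) stop("field has no '", ch, "' channel")
  }
  cells <- as.matrix(cells)
  k <- max(cells)
  if (k == 0) {
    return(data.frame(cell_id = integer(0), nucleus_count = integer(0),
                      total_intensity = numeric(0), surface_intensity = numeric(0),
                      transport_ratio = numeric(0), flags = character(0)))
  }
  surf <- field$channels$surface_marker
  tot <- field$channels$total_marker
  if (is.finite(bg_percentile)) {
    surf <- background_correct(surf, bg_percentile)
    tot <- background_correct(tot, bg_percentile)
  }
  idx <- cells > 0
  lab <- cells[idx]
  total_i <- as.numeric(rowsum(tot[idx], lab, reorder = TRUE))
  surf_i <- as.numeric(rowsum(surf[idx], lab, reorder = TRUE))
  nuc_count <- rep(NA_integer_, k)
  if (!is.null(nuclei)) nuc_count <- nuclei_per_cell(cells, nuclei)
  ratio <- ifelse(total_i > 0, surf_i / total_i, NA_real_)
  data.frame(cell_id = seq_len(k), nucleus_count = nuc_count,
             total_intensity = total_i, surface_intensity = surf_i,
             transport_ratio = ratio,
             flags = ifelse(total_i > 0, "", "non_positive_total"),
             stringsAsFactors = FALSE)
}

# number of nucleus labels whose pixels sit (by majority) in each cell
nuclei_per_cell <- function(cells, nuclei) {
  cells <- as.matrix(cells)
  nuclei <- as.matrix(nuclei)
  k <- max(cells)
  counts <- integer(k)
  nn <- max(nuclei)
  if (nn == 0 || k == 0) return(counts)
  for (n in seq_len(nn)) {
    owner <- cells[nuclei == n]
    owner <- owner[owner > 0]
    if (length(owner) == 0) next
    host <- as.integer(names(which.max(table(owner))))
    counts[host] <- counts[host] + 1L
  }
  counts
}

#' Fraction of multinucleated cells
#'
#' Fraction of cells containing two or more nuclei — the transfection-QC
#' readout on INCENP spots, where efficient knockdown blocks cytokinesis
#' and produces binucleated cells.
#'
#' @param cells,nuclei Aligned label matrices.
#' @return Fraction in `[0, 1]`; NA (with a warning) when there are no
#'   cells.
#' @export
multinucleation_fraction <- function(cells, nuclei) {
  k <- max(cells)
  if (k == 0) {
    warning("no cells in mask; multinucleation fraction undefined")
    return(NA_real_)
  }
  counts <- nuclei_per_cell(cells, nuclei)
  mean(counts >= 2)
}

#' Bin cells by expression level
#'
#' Splits cells into non-, low- and high-expressing by two thresholds on a
#' chosen intensity column. Bins are left-closed, right-open:
#' intensity < t1 is `non`, t1 <= intensity < t2 is `low`, >= t2 is `high`.
#' When `thresholds` is NULL the 33rd/66th percentiles of the data are used.
#'
#' @param records `CellRecord` data.frame.
#' @param channel Column to bin on (default `total_intensity`).
#' @param thresholds Numeric `c(t1, t2)` with t1 < t2, or NULL.
#' @return `records` with an `expression_bin` factor column.
#' @export
bin_cells_by_expression <- function(records, channel = "total_intensity",
                                    thresholds = NULL) {
  x <- records[[channel]]
  if (is.null(x)) stop("no column '", channel, "' in records")
  if (is.null(thresholds)) {
    thresholds <- stats::quantile(x, c(1, 2) / 3, names = FALSE)
  }
  if (length(thresholds) != 2 || !(thresholds[1] < thresholds[2])) {
    stop("thresholds must satisfy t1 < t2")
  }
  bin <- rep("low", length(x))
  bin[x < thresholds[1]] <- "non"
  bin[x >= thresholds[2]] <- "high"
  records$expression_bin <- factor(bin, levels = c("non", "low", "high"))
  records
}

#' Leak-corrected RUSH transport index
#'
#' The RUSH assay releases cargo with biotin; a non-release control (no
#' biotin) measures constitutive cargo leak. The transport index is the
#' mean release transport ratio minus the mean non-release (leak) ratio,
#' floored at zero, reported alongside the raw means.
#'
#' @param release_records,nonrelease_records `CellRecord` data.frames (or
#'   numeric ratio vectors).
#' @return List with `index`, `release_mean`, `leak_mean`, `n_release`,
#'   `n_nonrelease`.
#' @export
rush_transport_index <- function(release_records, nonrelease_records) {
  r <- if (is.data.frame(release_records)) release_records$transport_ratio else
    release_records
  l <- if (is.data.frame(nonrelease_records)) nonrelease_records$transport_ratio else
    nonrelease_records
  r <- r[is.finite(r)]
  l <- l[is.finite(l)]
  if (length(r) == 0 || length(l) == 0) {
    stop("release and non-release record sets must both be non-empty")
  }
  list(index = max(0, mean(r) - mean(l)), release_mean = mean(r),
       leak_mean = mean(l), n_release = length(r), n_nonrelease = length(l))
}

#' Write per-cell records to CSV
#'
#' @param records `CellRecord` data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
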