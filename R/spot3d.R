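#' Multichannel 3D confocal stack
#'
#' @param channels Named list of 3D numeric arrays (x, y, z), all the same
#'   shape, intensities >= 0.
#' @param z_spacing Optional axial spacing relative to pixel size (e.g. 3
#'   means one z-step spans three pixel widths); used to scale structuring
#'   elements anisotropically.
#' @return An object of class `volume_stack`.
#' @export
volume_stack <- function(channels, z_spacing = NA_real_) {
  if (is.array(channels) && length(dim(channels)) == 3) {
    channels <- list(structure = channels)
  }
  stopifnot(is.list(channels), length(channels) >= 1, !is.null(names(channels)))
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, integer(1)) != 3)) stop("channels must be 3D arrays")
  if (length(unique(dims)) != 1) stop("all channels must have the same shape")
  if (any(vapply(channels, function(a) any(a < 0), logical(1)))) {
    stop("intensities must be >= 0")
  }
  structure(list(channels = channels, z_spacing = z_spacing),
            class = "volume_stack")
}

#' Read a 3D multichannel stack from TIFF files
#'
#' Each channel comes from one multi-frame (z-stack) TIFF.
#'
#' @param paths Named character vector of per-channel TIFF paths.
#' @param z_spacing Optional axial spacing relative to pixel size.
#' @return A [volume_stack()].
#' @export
read_volume_stack <- function(paths, z_spacing = NA_real_) {
  stopifnot(!is.null(names(paths)))
  channels <- lapply(paths, function(p) {
    a <- as.array(EBImage::imageData(EBImage::readImage(p)))
    if (length(dim(a)) == 2) a <- array(a, dim = c(dim(a), 1))
    a
  })
  volume_stack(channels, z_spacing = z_spacing)
}

#' Write a label mask to TIFF
#'
#' Labels are stored as intensities scaled into [0, 1] (divided by the
#' maximum label); 2D masks write a single frame, 3D masks one frame per
#' z-plane.
#'
#' @param labels Integer label matrix or 3D array.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(labels, path) {
  mx <- max(labels, 1L)
  EBImage::writeImage(EBImage::Image(labels / mx), path, type = "tiff",
                      bits.per.sample = 16L)
  invisible(path)
}

.stack_channel <- function(stack, channel) {
  a <- if (inherits(stack, "volume_stack")) {
    stack$channels[[channel]] %||% stack$channels[[1]]
  } else stack
  stopifnot(length(dim(a)) == 3)
  a
}

# z-radius scaled by voxel anisotropy (at least 1 when the radius is >= 1)
.z_radius <- function(r, z_spacing) {
  if (!is.finite(z_spacing) || z_spacing <= 0) return(r)
  max(if (r >= 1) 1L else 0L, as.integer(round(r / z_spacing)))
}

#' Denoise and background-subtract a 3D stack
#'
#' Two 3D median filters: a small-radius filter suppresses voxel noise, a
#' large-radius filter estimates the smooth local background which is then
#' subtracted and the result clipped at zero. Structuring elements are
#' scaled anisotropically along z when the stack records a `z_spacing`.
#'
#' @param stack A `volume_stack` or 3D array.
#' @param noise_radius Radius (voxels) of the denoising median.
#' @param background_radius Radius of the background median; must exceed
#'   `noise_radius` (and the typical puncta radius).
#' @param channel Channel to process.
#' @return A `volume_stack` with the processed channel.
#' @export
preprocess_stack <- function(stack, noise_radius = 1, background_radius = 4,
                             channel = "structure") {
  if (noise_radius <= 0 || background_radius <= 0) {
    stop("filter radii must be positive")
  }
  if (background_radius <= noise_radius) {
    stop("background_radius must exceed noise_radius")
  }
  a <- .stack_channel(stack, channel)
  zs <- if (inherits(stack, "volume_stack")) stack$z_spacing else NA_real_
  d <- dim(a)
  den <- cpp_median_filter3(as.numeric(a), as.integer(d),
                            as.integer(noise_radius), as.integer(noise_radius),
                            as.integer(.z_radius(noise_radius, zs)))
  bg <- cpp_median_filter3(den, as.integer(d),
                           as.integer(background_radius), as.integer(background_radius),
                           as.integer(.z_radius(background_radius, zs)))
  out <- array(pmax(den - bg, 0), dim = d)
  volume_stack(stats::setNames(list(out), channel), z_spacing = zs)
}

#' Detect puncta seeds as 3D local maxima
#'
#' Strict local maxima of the (preprocessed) stack above an intensity
#' threshold, within a cube neighborhood (default 3x3x3); no two seeds can
#' share a neighborhood.
#'
#' @param stack Preprocessed `volume_stack` or 3D array.
#' @param min_seed_intensity Seed intensity threshold.
#' @param neighborhood_radius Half-width of the local-maximum neighborhood.
#' @param channel Channel to scan.
#' @return Integer matrix with columns `x`, `y`, `z` (1-based voxel
#'   coordinates), one row per seed; zero rows when none.
#' @export
detect_seeds <- function(stack, min_seed_intensity, neighborhood_radius = 1,
                         channel = "structure") {
  a <- .stack_channel(stack, channel)
  zs <- if (inherits(stack, "volume_stack")) stack$z_spacing else NA_real_
  d <- dim(a)
  idx <- cpp_local_maxima3(as.numeric(a), as.integer(d), min_seed_intensity,
                           as.integer(neighborhood_radius),
                           as.integer(neighborhood_radius),
                           as.integer(.z_radius(neighborhood_radius, zs)))
  coords <- arrayInd(idx, d)
  colnames(coords) <- c("x", "y", "z")
  coords
}

#' Segment puncta around seeds
#'
#' Voxels above `mask_threshold` form the foreground; each seed claims its
#' basin by intensity-ordered flooding (seeded watershed), so touching
#' structures are split along the intensity valley between their maxima.
#'
#' @param stack Preprocessed `volume_stack` or 3D array.
#' @param seeds Seed coordinate matrix from [detect_seeds()].
#' @param mask_threshold Foreground threshold; default half the weakest
#'   seed intensity.
#' @param channel Channel to segment.
#' @return Integer 3D label array (0 background, label i = seed i).
#' @export
segment_spots <- function(stack, seeds, mask_threshold = NULL,
                          channel = "structure") {
  a <- .stack_channel(stack, channel)
  d <- dim(a)
  if (is.null(seeds) || nrow(seeds) == 0) return(array(0L, dim = d))
  seed_idx <- seeds[, "x"] + d[1] * (seeds[, "y"] - 1) +
    d[1] * d[2] * (seeds[, "z"] - 1)
  if (is.null(mask_threshold)) {
    mask_threshold <- 0.5 * min(a[seed_idx])
  }
  mask <- as.numeric(a) > mask_threshold
  lab <- cpp_seeded_watershed3(as.numeric(a), as.integer(d), mask,
                               as.integer(seed_idx),
                               seq_len(nrow(seeds)))
  array(as.integer(lab), dim = d)
}

#' Split off large bright clusters (Golgi-like) from the spot mask
#'
#' Large bright connected regions — in the COPI channel these presumably
#' correspond to the Golgi complex — are segmented by thresholding in 3D
#' and removed from spot analysis. A spot label is reassigned to the
#' cluster mask when the majority of its voxels fall inside a cluster
#' region.
#'
#' @param labels Spot label array from [segment_spots()].
#' @param stack The (preprocessed) `volume_stack` or 3D array.
#' @param min_cluster_volume Minimum cluster volume in voxels; must exceed
#'   the typical spot volume.
#' @param cluster_threshold Intensity threshold for cluster segmentation;
#'   default Otsu on the positive voxels.
#' @param channel Channel to threshold.
#' @return List with `spots` (label array with clusters removed,
#'   relabelled contiguously) and `clusters` (label array of clusters).
#' @export
exclude_large_clusters <- function(labels, stack, min_cluster_volume = 300,
                                   cluster_threshold = NULL,
                                   channel = "structure") {
  a <- .stack_channel(stack, channel)
  d <- dim(a)
  if (is.null(cluster_threshold)) {
    pos <- a[a > 0]
    cluster_threshold <- if (length(pos) == 0) Inf else
      EBImage::otsu(EBImage::Image(.norm01(array(a, dim = c(d[1], d[2] * d[3]))))) * max(a)
  }
  fg <- as.numeric(a) > cluster_threshold
  cc <- cpp_label3(fg, as.integer(d), 6L)
  clusters <- array(0L, dim = d)
  if (max(cc) > 0) {
    vol <- tabulate(cc, nbins = max(cc))
    big <- which(vol >= min_cluster_volume)
    if (length(big) > 0) {
      map <- integer(max(cc))
      map[big] <- seq_along(big)
      nz <- cc > 0
      clusters[array(nz, dim = d)] <- map[cc[nz]]
    }
  }
  spots <- labels
  if (max(labels) > 0 && max(clusters) > 0) {
    for (l in seq_len(max(labels))) {
      inside <- labels == l
      if (sum(clusters[inside] > 0) > 0.5 * sum(inside)) spots[inside] <- 0L
    }
    # relabel contiguously
    left <- sort(unique(spots[spots > 0]))
    map <- integer(max(labels))
    map[left] <- seq_along(left)
    nz <- spots > 0
    spots[nz] <- map[spots[nz]]
  }
  list(spots = spots, clusters = clusters)
}

#' Per-cell puncta statistics
#'
#' Assigns each segmented spot to the cell containing its centroid and
#' reports, per cell, the number of structures, their integrated intensity,
#' and the integrated intensity of the entire cell. Spots whose centroid
#' falls on background are left unassigned but counted in the report.
#'
#' @param spot_labels 3D spot label array.
#' @param cells Cell label mask: either a 2D projected mask (applied to
#'   every z-plane) or a 3D label array.
#' @param stack `volume_stack` or 3D array of the measured channel.
#' @param channel Channel for intensities.
#' @return List with `per_cell` (data.frame `cell_id`, `structure_count`,
#'   `integrated_spot_intensity`, `cell_integrated_intensity`),
#'   `n_unassigned`, and `n_spots`.
#' @export
per_cell_spot_stats <- function(spot_labels, cells, stack,
                                channel = "structure") {
  a <- .stack_channel(stack, channel)
  d <- dim(a)
  cells <- as.array(cells)
  if (length(dim(cells)) == 2) {
    cells <- array(rep(as.integer(cells), d[3]), dim = d)
  }
  storage.mode(cells) <- "integer"
  k <- max(cells)
  n_spots <- max(spot_labels)
  count <- integer(max(k, 0))
  spot_int <- numeric(max(k, 0))
  unassigned <- 0L
  if (n_spots > 0) {
    nz <- which(spot_labels > 0)
    lab <- spot_labels[nz]
    coords <- arrayInd(nz, d)
    for (s in seq_len(n_spots)) {
      sel <- lab == s
      if (!any(sel)) next
      cen <- round(colMeans(coords[sel, , drop = FALSE]))
      cell <- cells[cen[1], cen[2], cen[3]]
      if (cell == 0) {
        unassigned <- unassigned + 1L
      } else {
        count[cell] <- count[cell] + 1L
        spot_int[cell] <- spot_int[cell] + sum(a[nz[sel]])
      }
    }
  }
  cell_int <- numeric(max(k, 0))
  if (k > 0) {
    inside <- cells > 0
    cell_int_tab <- rowsum(a[inside], cells[inside], reorder = TRUE)
    cell_int[as.integer(rownames(cell_int_tab))] <- as.numeric(cell_int_tab)
  }
  list(per_cell = data.frame(cell_id = seq_len(max(k, 0)),
                             structure_count = count,
                             integrated_spot_intensity = spot_int,
                             cell_integrated_intensity = cell_int),
       n_unassigned = unassigned, n_spots = n_spots)
}

#' Condition-level puncta summary with a minimum-cell guard
#'
#' Pools per-cell spot statistics across images of one condition and
#' refuses to summarize (returns a flagged result) when fewer than
#' `min_cells` cells were quantified.
#'
#' @param per_cell_tables List (or single data.frame) of `per_cell` tables
#'   from [per_cell_spot_stats()].
#' @param min_cells Minimum quantified cells per condition (default 100).
#' @return List with `n_cells`, `mean_count`, `mean_spot_intensity`,
#'   `mean_cell_intensity`, `sufficient` and `flags`.
#' @export
condition_spot_summary <- function(per_cell_tables, min_cells = 100) {
  if (is.data.frame(per_cell_tables)) per_cell_tables <- list(per_cell_tables)
  df <- do.call(rbind, per_cell_tables)
  n <- nrow(df)
  if (n < min_cells) {
    return(list(n_cells = n, mean_count = NA_real_,
                mean_spot_intensity = NA_real_, mean_cell_intensity = NA_real_,
                sufficient = FALSE, flags = "insufficient_cells"))
  }
  list(n_cells = n, mean_count = mean(df$structure_count),
       mean_spot_intensity = mean(df$integrated_spot_intensity),
       mean_cell_intensity = mean(df$cell_integrated_intensity),
       sufficient = TRUE, flags = "")
}

#' Count puncta in a stack end-to-end
#'
#' Convenience pipeline: preprocess, seed detection, seeded segmentation,
#' optional Golgi-cluster exclusion.
#'
#' @param stack Raw `volume_stack` or 3D array.
#' @param min_seed_intensity Seed threshold on the preprocessed stack.
#' @param noise_radius,background_radius See [preprocess_stack()].
#' @param exclude_clusters Remove large bright clusters before counting.
#' @param min_cluster_volume See [exclude_large_clusters()].
#' @param channel Channel name.
#' @return List with `labels`, `clusters`, `seeds`, `count`.
#' @export
count_spots <- function(stack, min_seed_intensity, noise_radius = 1,
                        background_radius = 4, exclude_clusters = TRUE,
                        min_cluster_volume = 300, channel = "structure") {
  pre <- preprocess_stack(stack, noise_radius, background_radius, channel)
  seeds <- detect_seeds(pre, min_seed_intensity, channel = channel)
  labels <- segment_spots(pre, seeds, mask_threshold = 0.5 * min_seed_intensity,
                          channel = channel)
  clusters <- array(0L, dim = dim(.stack_channel(pre, channel)))
  if (exclude_clusters && nrow(seeds) > 0) {
    ex <- exclude_large_clusters(labels, pre, min_cluster_volume,
                                 cluster_threshold = 0.5 * min_seed_intensity,
                                 channel = channel)
    labels <- ex$spots
    clusters <- ex$clusters
  }
  list(labels = labels, clusters = clusters, seeds = seeds,
       count = max(labels))
}
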