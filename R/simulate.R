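#' Ground truth for a simulated double-knockdown screen
#'
#' Fixes every generative parameter of the simulated screen: per-siRNA main
#' effects on the transport ratio, background effects, interaction
#' (synergy) terms, a smooth spatial plate gradient, per-cell noise and
#' cell counts. Given the truth object and a seed, the simulated data are
#' fully determined.
#'
#' Defaults emulate the screen design: base transport ratio 0.5, per-cell
#' Gaussian noise sd 0.15, ~200 cells per spot, a low-order polynomial
#' plate gradient with amplitude 20% of the base ratio, sample-library main
#' effects with sd 0.08 ratio units, strong COPI positive controls (-0.3),
#' near-neutral SEC23A/SEC23B single knockdowns (paralog compensation) with
#' a strong built-in SEC23A x SEC23B interaction, and `n_synergy` planted
#' synergistic sample pairs with small single effects.
#'
#' @param sirnas Sample siRNA identifiers.
#' @param seed Integer seed fixing effect draws and gradient shape.
#' @param n_synergy Number of planted synergistic (siRNA, background) pairs.
#' @param interaction Interaction effect of planted pairs (ratio units).
#' @param synergy_single_max Planted pairs' single effects are drawn
#'   uniformly within +/- this bound.
#' @param effect_sd Sd of the remaining sample siRNAs' main effects.
#' @param base_ratio,noise_sd,cells_per_spot,gradient_amplitude Generative
#'   constants (ratio units; `gradient_amplitude` as a fraction of
#'   `base_ratio`).
#' @param null_effects If TRUE all main/interaction effects are zero (the
#'   gradient and noise remain): a null plate.
#' @return An object of class `screen_truth`.
#' @export
screen_truth <- function(sirnas = sprintf("siCSK%04d", 1:848), seed = 1,
                         n_synergy = 10, interaction = -0.25,
                         synergy_single_max = 0.05, effect_sd = 0.08,
                         base_ratio = 0.5, noise_sd = 0.15,
                         cells_per_spot = 200, gradient_amplitude = 0.2,
                         null_effects = FALSE) {
  set.seed(seed)
  main <- stats::rnorm(length(sirnas), 0, effect_sd)
  names(main) <- sirnas
  interactions <- numeric(0)
  synergy_pairs <- data.frame(sirna_id = character(0), background = character(0))
  if (n_synergy > 0) {
    planted <- sample(sirnas, n_synergy)
    main[planted] <- stats::runif(n_synergy, -synergy_single_max, synergy_single_max)
    bg <- rep(c("SEC23A", "SEC23B"), length.out = n_synergy)
    interactions <- stats::setNames(rep(interaction, n_synergy),
                                    paste(planted, bg, sep = "|"))
    synergy_pairs <- data.frame(sirna_id = planted, background = bg,
                                stringsAsFactors = FALSE)
  }
  # control siRNAs: strong COPI inhibitors; non-targeting, INCENP and the
  # SEC23 singles are transport-neutral (screen conditions are titrated so
  # that SEC23A or SEC23B knockdown alone has no transport phenotype),
  # while co-depletion of both paralogs inhibits strongly
  main <- c(main, siCOPB1 = -0.3, siCOPG1 = -0.3, siScramble = 0, siNeg9 = 0,
            siINCENP = 0, siSEC23A = 0, siSEC23B = 0)
  interactions <- c(interactions,
                    "siSEC23B|SEC23A" = -0.3, "siSEC23A|SEC23B" = -0.3)
  background_effects <- c(SEC23A = 0, SEC23B = 0, control = 0)
  grad_coef <- stats::rnorm(5)
  if (null_effects) {
    main[] <- 0
    interactions[] <- 0
    background_effects[] <- 0
    synergy_pairs <- synergy_pairs[0, ]
  }
  structure(
    list(main_effects = main, interactions = interactions,
         background_effects = background_effects,
         synergy_pairs = synergy_pairs,
         gradient_coef = grad_coef,
         gradient_amplitude = gradient_amplitude,
         base_ratio = base_ratio, noise_sd = noise_sd,
         cells_per_spot = cells_per_spot, seed = seed),
    class = "screen_truth")
}

#' Evaluate a truth's plate gradient on a grid
#'
#' Low-order polynomial surface in the 0-based grid coordinates, rescaled
#' so its largest magnitude equals `gradient_amplitude * base_ratio`.
#'
#' @param truth A `screen_truth`.
#' @param n_rows,n_cols Grid dimensions.
#' @return A `n_rows` x `n_cols` matrix of additive ratio offsets.
#' @export
plate_gradient <- function(truth, n_rows, n_cols) {
  x <- if (n_rows > 1) 2 * (0:(n_rows - 1)) / (n_rows - 1) - 1 else 0
  y <- if (n_cols > 1) 2 * (0:(n_cols - 1)) / (n_cols - 1) - 1 else 0
  a <- truth$gradient_coef
  g <- outer(x, y, function(x, y) a[1] * x + a[2] * y + a[3] * x * y +
               a[4] * x^2 + a[5] * y^2)
  mx <- max(abs(g))
  if (mx == 0) return(g)
  g / mx * truth$gradient_amplitude * truth$base_ratio
}

#' Simulate the per-cell ratio table of one plate
#'
#' Each spot receives a Poisson number of cells; each cell's transport
#' ratio is `base + main effect(siRNA) + background effect(chamber) +
#' interaction(siRNA, background) + gradient(row, col) + N(0, noise_sd)`,
#' truncated at zero. Byte-identical output for identical layout, truth and
#' seed.
#'
#' @param layout A `plate_layout` (its `background` selects the background
#'   effect and interaction terms).
#' @param truth A `screen_truth`.
#' @param seed Integer seed.
#' @return Data.frame with `row`, `col`, `sirna_id`, `cell_id`,
#'   `transport_ratio`.
#' @export
simulate_plate <- function(layout, truth, seed = 1) {
  stopifnot(inherits(layout, "plate_layout"), inherits(truth, "screen_truth"))
  set.seed(seed)
  sp <- layout$spots
  g <- plate_gradient(truth, layout$n_rows, layout$n_cols)
  main <- truth$main_effects[sp$sirna_id]
  main[is.na(main)] <- 0
  inter <- truth$interactions[paste(sp$sirna_id, layout$background, sep = "|")]
  inter[is.na(inter)] <- 0
  mu <- truth$base_ratio + main + inter +
    truth$background_effects[[layout$background]] +
    g[cbind(sp$row + 1L, sp$col + 1L)]
  n <- stats::rpois(nrow(sp), truth$cells_per_spot)
  i <- rep(seq_len(nrow(sp)), n)
  ratio <- pmax(mu[i] + stats::rnorm(length(i), 0, truth$noise_sd), 0)
  data.frame(row = sp$row[i], col = sp$col[i], sirna_id = sp$sirna_id[i],
             cell_id = sequence(n), transport_ratio = ratio,
             stringsAsFactors = FALSE)
}

#' Serialize / restore a screen truth
#'
#' @param truth A `screen_truth`.
#' @param path JSON path.
#' @return `path` invisibly; `read_truth` returns the `screen_truth`.
#' @export
write_truth <- function(truth, path) {
  obj <- unclass(truth)
  # named vectors go out as JSON objects so names survive the round trip
  for (f in c("main_effects", "interactions", "background_effects")) {
    obj[[f]] <- as.list(obj[[f]])
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("main_effects", "interactions", "background_effects")) {
    obj[[f]] <- unlist(obj[[f]])
    if (is.null(obj[[f]])) obj[[f]] <- numeric(0)
  }
  obj$synergy_pairs <- as.data.frame(obj$synergy_pairs,
                                     stringsAsFactors = FALSE)
  structure(obj, class = "screen_truth")
}

# -- image simulators --------------------------------------------------------

.disk_mask <- function(nrow, ncol, cx, cy, r) {
  outer(seq_len(nrow), seq_len(ncol), function(x, y) (x - cx)^2 + (y - cy)^2 <= r^2)
}

#' Simulate a multichannel 2D cell field with ground truth
#'
#' Places round cells on a jittered grid; each cell carries a nucleus (two
#' disjoint nuclei for binucleated cells), a total-marker disk of per-cell
#' intensity, and a surface-marker channel whose per-cell intensity is the
#' programmed transport ratio times the total signal. Gaussian noise and a
#' flat baseline are added to all channels.
#'
#' @param n_cells Number of cells.
#' @param ratios Programmed per-cell transport ratios (recycled).
#' @param binucleation_fraction Fraction of cells with two nuclei.
#' @param dim Field dimensions (pixels).
#' @param cell_radius,nucleus_radius Object radii (pixels).
#' @param total_intensity Mean per-pixel total-marker intensity inside a
#'   cell.
#' @param noise_sd Gaussian noise sd (intensity units).
#' @param baseline Flat background level.
#' @param seed Integer seed.
#' @return List with `field` (a [channel_field()]), `truth` (per-cell
#'   table: centers, ratio, binucleated), `cell_mask`, `nucleus_mask`
#'   (ground-truth label matrices).
#' @export
simulate_cell_field <- function(n_cells = 9, ratios = 0.5,
                                binucleation_fraction = 0,
                                dim = c(96, 96), cell_radius = 11,
                                nucleus_radius = 3.5, total_intensity = 100,
                                noise_sd = 2, baseline = 1, seed = 1) {
  set.seed(seed)
  per_row <- ceiling(sqrt(n_cells))
  pitch <- floor(min(dim) / per_row)
  stopifnot(pitch >= 2 * cell_radius - 2)
  centers <- expand.grid(ix = seq_len(per_row), iy = seq_len(per_row))[seq_len(n_cells), ]
  cx <- (centers$ix - 0.5) * pitch + stats::runif(n_cells, -1.5, 1.5)
  cy <- (centers$iy - 0.5) * pitch + stats::runif(n_cells, -1.5, 1.5)
  ratios <- rep(ratios, length.out = n_cells)
  n_bi <- round(binucleation_fraction * n_cells)
  binucleated <- seq_len(n_cells) %in% sample(n_cells, n_bi)

  cell_mask <- matrix(0L, dim[1], dim[2])
  nucleus_mask <- matrix(0L, dim[1], dim[2])
  total <- matrix(0, dim[1], dim[2])
  surface <- matrix(0, dim[1], dim[2])
  nucleus <- matrix(0, dim[1], dim[2])
  next_nuc <- 0L
  for (i in seq_len(n_cells)) {
    cm <- .disk_mask(dim[1], dim[2], cx[i], cy[i], cell_radius)
    cell_mask[cm] <- i
    total[cm] <- total_intensity
    surface[cm] <- ratios[i] * total_intensity
    offs <- if (binucleated[i]) {
      cbind(c(-(nucleus_radius + 1.5), nucleus_radius + 1.5), c(0, 0))
    } else cbind(0, 0)
    for (k in seq_len(nrow(offs))) {
      nm <- .disk_mask(dim[1], dim[2], cx[i] + offs[k, 1], cy[i] + offs[k, 2],
                       nucleus_radius)
      next_nuc <- next_nuc + 1L
      nucleus_mask[nm] <- next_nuc
      nucleus[nm] <- total_intensity
    }
  }
  noisy <- function(m) pmax(m + baseline + stats::rnorm(length(m), 0, noise_sd), 0)
  field <- channel_field(list(nucleus = noisy(nucleus),
                              total_marker = noisy(total),
                              surface_marker = noisy(surface)))
  list(field = field,
       truth = data.frame(cell_id = seq_len(n_cells), x = cx, y = cy,
                          ratio = ratios, binucleated = binucleated),
       cell_mask = cell_mask, nucleus_mask = nucleus_mask)
}

#' Simulate a 3D puncta stack with ground truth
#'
#' Gaussian puncta at recorded coordinates over a flat background, an
#' optional large bright ellipsoidal cluster (Golgi-like), and Gaussian
#' noise at a set signal-to-noise ratio (SNR = punctum amplitude / noise
#' sd).
#'
#' @param n_spots Number of puncta.
#' @param dim Stack dimensions `c(x, y, z)` in voxels.
#' @param amplitude Punctum peak amplitude above background.
#' @param sigma Punctum Gaussian sd in voxels.
#' @param snr Signal-to-noise ratio; `Inf` for noise-free.
#' @param min_separation Minimum center-to-center spacing in voxels.
#' @param cluster Add a Golgi-like cluster?
#' @param cluster_radius Ellipsoid semi-axes `c(rx, ry, rz)`.
#' @param background Flat background level.
#' @param seed Integer seed.
#' @return List with `stack` (a [volume_stack()]), `truth` (spot centers,
#'   amplitude, cluster center/radii or NULL).
#' @export
simulate_spot_stack <- function(n_spots = 10, dim = c(48, 48, 16),
                                amplitude = 100, sigma = 1.2, snr = 10,
                                min_separation = 7, cluster = FALSE,
                                cluster_radius = c(7, 7, 4),
                                background = 10, seed = 1) {
  set.seed(seed)
  margin <- 5
  centers <- matrix(NA_real_, 0, 3)
  guard <- 0
  cluster_center <- if (cluster) c(dim[1] - cluster_radius[1] - 3,
                                   dim[2] - cluster_radius[2] - 3,
                                   ceiling(dim[3] / 2)) else NULL
  while (nrow(centers) < n_spots && guard < 20000) {
    guard <- guard + 1
    p <- c(stats::runif(1, margin, dim[1] - margin),
           stats::runif(1, margin, dim[2] - margin),
           stats::runif(1, 4, dim[3] - 3))
    ok <- nrow(centers) == 0 ||
      min(sqrt(colSums((t(centers) - p)^2))) >= min_separation
    if (ok && cluster) {
      ok <- sqrt(sum(((p - cluster_center) / (cluster_radius + sigma * 3))^2)) > 1.6
    }
    if (ok) centers <- rbind(centers, p)
  }
  if (nrow(centers) < n_spots) stop("could not place ", n_spots, " puncta")
  a <- array(background, dim = dim)
  ax <- seq_len(dim[1]); ay <- seq_len(dim[2]); az <- seq_len(dim[3])
  for (s in seq_len(n_spots)) {
    gx <- exp(-(ax - centers[s, 1])^2 / (2 * sigma^2))
    gy <- exp(-(ay - centers[s, 2])^2 / (2 * sigma^2))
    gz <- exp(-(az - centers[s, 3])^2 / (2 * sigma^2))
    a <- a + amplitude * (gx %o% gy %o% gz)
  }
  if (cluster) {
    ex <- ((ax - cluster_center[1]) / cluster_radius[1])^2
    ey <- ((ay - cluster_center[2]) / cluster_radius[2])^2
    ez <- ((az - cluster_center[3]) / cluster_radius[3])^2
    inside <- outer(outer(ex, ey, `+`), ez, `+`) <= 1
    a[inside] <- a[inside] + 1.2 * amplitude
  }
  if (is.finite(snr)) {
    a <- pmax(a + array(stats::rnorm(prod(dim), 0, amplitude / snr), dim = dim), 0)
  }
  list(stack = volume_stack(list(structure = a)),
       truth = list(centers = centers, amplitude = amplitude, sigma = sigma,
                    cluster_center = cluster_center,
                    cluster_radius = if (cluster) cluster_radius else NULL))
}

.ellipse_mask <- function(nrow, ncol, cx, cy, a, b, theta) {
  ct <- cos(theta); st <- sin(theta)
  outer(seq_len(nrow), seq_len(ncol), function(x, y) {
    u <- (x - cx) * ct + (y - cy) * st
    v <- -(x - cx) * st + (y - cy) * ct
    (u / a)^2 + (v / b)^2 <= 1
  })
}

#' Simulate a focal-adhesion z-stack with ground truth
#'
#' Elongated adhesion ellipses drawn sharp in one designated in-focus slice
#' (the ventral plane); other slices carry attenuated, strongly blurred
#' copies (out-of-focus light). A separate 2D nucleus image provides the
#' per-cell normalizer. Gaussian noise at `1/snr` of the adhesion amplitude
#' is added to every slice.
#'
#' @param n_fa Number of adhesions.
#' @param dim Stack dimensions `c(x, y, z)`.
#' @param focus_plane 1-based index of the sharp slice.
#' @param major,minor Mean ellipse half-axes (pixels).
#' @param size_scale Multiplies both half-axes (e.g. 2 for the "enlarged
#'   adhesions" condition; area scales ~`size_scale^2`).
#' @param amplitude Adhesion intensity.
#' @param snr Signal-to-noise ratio.
#' @param n_nuclei Nuclei drawn on the nucleus image.
#' @param seed Integer seed.
#' @return List with `stack` (a [volume_stack()] with channel `adhesion`),
#'   `nucleus` (2D image), `truth` (focus plane, per-adhesion areas in
#'   pixels, total area, n_nuclei).
#' @export
simulate_fa_stack <- function(n_fa = 12, dim = c(64, 64, 9), focus_plane = 5,
                              major = 4, minor = 1.6, size_scale = 1,
                              amplitude = 100, snr = 10, n_nuclei = 3,
                              seed = 1) {
  set.seed(seed)
  stopifnot(focus_plane >= 1, focus_plane <= dim[3])
  sharp <- matrix(0, dim[1], dim[2])
  areas <- numeric(n_fa)
  placed <- matrix(NA_real_, 0, 2)
  for (i in seq_len(n_fa)) {
    repeat {
      cx <- stats::runif(1, 8, dim[1] - 8)
      cy <- stats::runif(1, 8, dim[2] - 8)
      if (nrow(placed) == 0 ||
          min(sqrt(colSums((t(placed) - c(cx, cy))^2))) > 2.5 * major * size_scale)
        break
    }
    placed <- rbind(placed, c(cx, cy))
    a <- size_scale * major * stats::runif(1, 0.8, 1.2)
    b <- size_scale * minor * stats::runif(1, 0.8, 1.2)
    m <- .ellipse_mask(dim[1], dim[2], cx, cy, a, b, stats::runif(1, 0, pi))
    areas[i] <- sum(m & sharp == 0)
    sharp[m] <- amplitude
  }
  stack <- array(0, dim = dim)
  img <- EBImage::Image(sharp / max(max(sharp), 1))
  for (z in seq_len(dim[3])) {
    dz <- abs(z - focus_plane)
    stack[, , z] <- if (dz == 0) sharp else {
      # blur saturates a few slices out (kernel must stay inside the image)
      blur <- EBImage::gblur(img, sigma = 2.5 * min(dz, 3))
      as.matrix(EBImage::imageData(blur)) * max(sharp) / (1 + dz)
    }
  }
  if (is.finite(snr)) {
    stack <- pmax(stack + array(stats::rnorm(prod(dim), 0, amplitude / snr),
                                dim = dim), 0)
  }
  nucleus <- matrix(0, dim[1], dim[2])
  nuc_centers <- matrix(NA_real_, 0, 2)
  for (k in seq_len(n_nuclei)) {
    # best-effort spacing: dense fields accept the last candidate tried
    for (try in 1:200) {
      p <- c(stats::runif(1, 10, dim[1] - 10), stats::runif(1, 10, dim[2] - 10))
      if (nrow(nuc_centers) == 0 ||
          min(sqrt(colSums((t(nuc_centers) - p)^2))) > 13) break
    }
    nuc_centers <- rbind(nuc_centers, p)
    nucleus <- nucleus + amplitude * .disk_mask(dim[1], dim[2], p[1], p[2], 4)
  }
  nucleus <- pmax(nucleus + stats::rnorm(length(nucleus), 0, amplitude / snr), 0)
  list(stack = volume_stack(list(adhesion = stack)), nucleus = nucleus,
       truth = list(focus_plane = focus_plane, areas = areas,
                    total_area = sum(areas), n_nuclei = n_nuclei))
}
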