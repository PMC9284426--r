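test_that("volume_stack validates channel shapes", {
  a <- array(1, c(8, 8, 4))
  expect_s3_class(volume_stack(list(structure = a)), "volume_stack")
  expect_error(volume_stack(list(a = a, b = array(1, c(8, 8, 5)))), "same shape")
  expect_error(volume_stack(list(a = a - 2)), ">= 0")
})

test_that("preprocessing removes flat and smooth backgrounds but keeps puncta", {
  flat <- volume_stack(list(structure = array(37, c(16, 16, 8))))
  expect_true(all(preprocess_stack(flat)$channels$structure == 0))
  expect_error(preprocess_stack(flat, noise_radius = 0), "positive")
  expect_error(preprocess_stack(flat, noise_radius = 3, background_radius = 2),
               "exceed")

  # one broad punctum on a sloping background: with a background window
  # well above the punctum size the peak survives (>=80%) and the
  # background is flattened to under 5% of it
  a <- array(0, c(40, 40, 16))
  for (z in 1:16) a[, , z] <- outer(1:40, 1:40, function(x, y) 5 + 0.3 * x + 0.2 * y)
  for (z in 1:16) {
    a[, , z] <- a[, , z] + 100 * exp(-((col(a[, , 1]) - 20)^2 +
                                         (row(a[, , 1]) - 20)^2) / (2 * 3^2)) *
      exp(-(z - 8)^2 / (2 * 3^2))
  }
  pre <- preprocess_stack(volume_stack(list(structure = a)),
                          background_radius = 8)$channels$structure
  expect_gt(max(pre), 80)
  expect_lt(max(pre[1:8, 1:8, ]), 0.05 * max(pre))
})

test_that("seed detection finds puncta at their centers and nothing in blanks", {
  sim <- simulate_spot_stack(n_spots = 10, snr = Inf, seed = 21)
  pre <- preprocess_stack(sim$stack)
  seeds <- detect_seeds(pre, 35)
  expect_equal(nrow(seeds), 10)
  # each seed within 1 voxel of a distinct true center
  d <- as.matrix(dist(rbind(seeds, sim$truth$centers)))[1:10, 11:20]
  expect_true(all(apply(d, 1, min) <= sqrt(3) + 1e-9))
  expect_equal(length(unique(apply(d, 1, which.min))), 10)

  blank <- volume_stack(list(structure = array(0, c(16, 16, 8))))
  expect_equal(nrow(detect_seeds(blank, 10)), 0)

  # two nearby puncta with distinct maxima stay two seeds
  b <- array(0, c(20, 20, 8))
  b[8, 10, 4] <- 100
  b[11, 10, 4] <- 90
  expect_equal(nrow(detect_seeds(b, 50)), 2)
})

test_that("raising the seed threshold never increases the seed count", {
  sim <- simulate_spot_stack(n_spots = 8, snr = 5, seed = 30)
  pre <- preprocess_stack(sim$stack)
  counts <- vapply(seq(5, 80, by = 5),
                   function(th) nrow(detect_seeds(pre, th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("spot segmentation labels each seed's basin and splits touching
           structures along the valley", {
  sim <- simulate_spot_stack(n_spots = 10, snr = Inf, seed = 21)
  pre <- preprocess_stack(sim$stack)
  seeds <- detect_seeds(pre, 35)
  lab <- segment_spots(pre, seeds)
  expect_equal(max(lab), 10)
  vols <- tabulate(lab[lab > 0], nbins = 10)
  # ten identical puncta: all basin volumes within 30% of their median
  expect_true(all(abs(vols / median(vols) - 1) < 0.3))

  expect_equal(max(segment_spots(pre, seeds[0, , drop = FALSE])), 0)

  # two touching puncta: two labels, each containing its own maximum
  b <- array(0, c(24, 24, 8))
  g <- function(cx) outer(1:24, 1:24, function(x, y)
    exp(-((x - cx)^2 + (y - 12)^2) / (2 * 1.5^2)))
  for (z in 1:8) b[, , z] <- 100 * (g(10) + 0.9 * g(14)) * exp(-(z - 4)^2 / 4.5)
  s2 <- detect_seeds(b, 40)
  expect_equal(nrow(s2), 2)
  l2 <- segment_spots(b, s2, mask_threshold = 20)
  expect_equal(max(l2), 2)
  expect_true(l2[10, 12, 4] != l2[14, 12, 4])
})

test_that("large bright clusters are excluded from spot analysis", {
  sim <- simulate_spot_stack(n_spots = 5, snr = Inf, cluster = TRUE, seed = 22)
  out <- count_spots(sim$stack, min_seed_intensity = 35)
  expect_equal(out$count, 5)
  expect_equal(max(out$clusters), 1)

  # without a cluster the spot mask is untouched and no cluster is reported
  plain <- simulate_spot_stack(n_spots = 5, snr = Inf, seed = 22)
  out2 <- count_spots(plain$stack, min_seed_intensity = 35)
  expect_equal(out2$count, 5)
  expect_equal(max(out2$clusters), 0)

  # cluster-only stack: zero spots after exclusion
  only <- simulate_spot_stack(n_spots = 0, snr = Inf, cluster = TRUE, seed = 23)
  out3 <- count_spots(only$stack, min_seed_intensity = 35)
  expect_equal(out3$count, 0)
  expect_gte(max(out3$clusters), 1)
})

test_that("per-cell statistics assign spots by centroid and conserve counts", {
  sim <- simulate_spot_stack(n_spots = 10, snr = Inf, seed = 21)
  cs <- count_spots(sim$stack, min_seed_intensity = 35)
  cells <- matrix(1L, 48, 48)
  cells[, 25:48] <- 2L
  st <- per_cell_spot_stats(cs$labels, cells, sim$stack)
  truth_split <- c(sum(sim$truth$centers[, 2] <= 24.5),
                   sum(sim$truth$centers[, 2] > 24.5))
  expect_equal(st$per_cell$structure_count, truth_split)
  expect_equal(sum(st$per_cell$structure_count) + st$n_unassigned, st$n_spots)
  expect_true(all(st$per_cell$integrated_spot_intensity <=
                    st$per_cell$cell_integrated_intensity))

  # spots in unlabelled background are counted as unassigned
  half <- cells
  half[, 1:24] <- 0L
  st2 <- per_cell_spot_stats(cs$labels, half, sim$stack)
  expect_equal(st2$n_unassigned, truth_split[1])

  none <- per_cell_spot_stats(array(0L, c(48, 48, 16)), cells, sim$stack)
  expect_true(all(none$per_cell$structure_count == 0))
})

test_that("condition summaries refuse fewer than the minimum cells", {
  tab <- data.frame(cell_id = 1:40, structure_count = 5,
                    integrated_spot_intensity = 10, cell_integrated_intensity = 100)
  s <- condition_spot_summary(tab, min_cells = 100)
  expect_false(s$sufficient)
  expect_equal(s$flags, "insufficient_cells")
  s2 <- condition_spot_summary(list(tab, tab, tab), min_cells = 100)
  expect_true(s2$sufficient)
  expect_equal(s2$mean_count, 5)
})

test_that("spot counts agree with brute-force connected components on sparse
           stacks", {
  for (seed in 1:5) {
    sim <- simulate_spot_stack(n_spots = 3, dim = c(24, 24, 10), snr = Inf,
                               min_separation = 9, seed = seed)
    a <- sim$stack$channels$structure
    cs <- count_spots(sim$stack, min_seed_intensity = 35)
    expect_equal(cs$count, brute_cc_count(a > 35))
  }
})

test_that("stacks and label masks round-trip through TIFF", {
  sim <- simulate_spot_stack(n_spots = 4, dim = c(24, 24, 10), snr = Inf,
                             seed = 33)
  a <- sim$stack$channels$structure
  path <- tempfile(fileext = ".tif")
  EBImage::writeImage(EBImage::Image(a / max(a)), path, type = "tiff",
                      bits.per.sample = 16L)
  back <- read_volume_stack(c(structure = path))
  expect_equal(dim(back$channels$structure), dim(a))
  expect_lt(max(abs(back$channels$structure - a / max(a))), 1e-4)

  cs <- count_spots(sim$stack, min_seed_intensity = 35)
  mpath <- tempfile(fileext = ".tif")
  write_label_mask(cs$labels, mpath)
  expect_true(file.exists(mpath))
  lab_back <- round(read_volume_stack(c(m = mpath))$channels$m * max(cs$labels))
  expect_equal(array(as.integer(lab_back), dim(cs$labels)), cs$labels)
})
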