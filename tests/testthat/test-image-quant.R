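test_that("channel_field validates shapes and non-negative intensities", {
  m <- matrix(1, 10, 10)
  expect_s3_class(channel_field(list(nucleus = m)), "channel_field")
  expect_error(channel_field(list(a = m, b = matrix(1, 5, 5))), "same shape")
  expect_error(channel_field(list(a = m - 2)), ">= 0")
})

test_that("nucleus segmentation finds blobs, splits touching pairs, and
           returns contiguous labels", {
  sim <- simulate_cell_field(n_cells = 5, seed = 2)
  nuc <- segment_nuclei(sim$field)
  expect_equal(max(nuc), 5)
  expect_equal(sort(unique(as.vector(nuc))), 0:5)

  blank <- channel_field(list(nucleus = matrix(0, 40, 40)))
  expect_equal(max(segment_nuclei(blank)), 0)

  # two overlapping blobs with two intensity maxima split into two labels
  m <- matrix(0, 60, 60)
  m[.disk_mask_test(60, 25, 30, 8)] <- 100
  m[.disk_mask_test(60, 37, 30, 8)] <- 100
  two <- segment_nuclei(channel_field(list(nucleus = m)))
  expect_equal(max(two), 2)
})

test_that("cell segmentation partitions the foreground around nucleus seeds", {
  sim <- simulate_cell_field(n_cells = 9, seed = 3)
  nuc <- segment_nuclei(sim$field)
  cells <- segment_cells(sim$field, nuc)
  expect_equal(max(cells), max(nuc))
  # each cell contains exactly its seed nucleus
  for (k in seq_len(max(nuc))) {
    owners <- unique(cells[nuc == k])
    expect_equal(owners, k)
  }
  # cells are disjoint by construction of a label mask; every nucleus pixel
  # is inside a cell
  expect_true(all(cells[nuc > 0] > 0))
  # single nucleus in uniform foreground claims all of it
  f <- channel_field(list(nucleus = matrix(0, 30, 30),
                          total_marker = matrix(50, 30, 30)))
  one <- matrix(0L, 30, 30)
  one[14:16, 14:16] <- 1L
  cells1 <- segment_cells(f, one, foreground = matrix(TRUE, 30, 30))
  expect_true(all(cells1 == 1L))
})

test_that("per-cell transport ratios are background-corrected sums", {
  # exact arithmetic on a constructed field
  tot <- matrix(0, 20, 20)
  sur <- matrix(0, 20, 20)
  cells <- matrix(0L, 20, 20)
  cells[2:6, 2:6] <- 1L
  tot[2:6, 2:6] <- 4     # sums to 100
  sur[2:6, 2:6] <- 2     # sums to 50
  f <- channel_field(list(total_marker = tot, surface_marker = sur))
  rec <- per_cell_transport_ratio(f, cells, bg_percentile = NA)
  expect_equal(rec$transport_ratio, 0.5)
  expect_equal(rec$total_intensity, 100)

  # zero total intensity flags the cell
  cells2 <- cells
  cells2[12:14, 12:14] <- 2L
  rec2 <- per_cell_transport_ratio(f, cells2, bg_percentile = NA)
  expect_true(is.na(rec2$transport_ratio[2]))
  expect_equal(rec2$flags[2], "non_positive_total")

  # programmed per-cell ratios recovered end to end
  sim <- simulate_cell_field(n_cells = 9, ratios = c(0.2, 0.6, 0.9), seed = 4)
  nuc <- segment_nuclei(sim$field)
  cl <- segment_cells(sim$field, nuc)
  got <- per_cell_transport_ratio(sim$field, cl, nuc)
  expect_equal(nrow(got), 9)
  expect_true(all(abs(sort(got$transport_ratio) -
                        sort(rep(c(0.2, 0.6, 0.9), 3))) < 0.05))
})

test_that("transport ratio is invariant to common intensity scaling and to
           added uniform background under correction", {
  sim <- simulate_cell_field(n_cells = 4, ratios = 0.45, seed = 6)
  cl <- sim$cell_mask
  base <- per_cell_transport_ratio(sim$field, cl, bg_percentile = NA)
  scaled <- channel_field(lapply(sim$field$channels, function(m) 7.3 * m))
  expect_equal(per_cell_transport_ratio(scaled, cl, bg_percentile = NA)$transport_ratio,
               base$transport_ratio, tolerance = 1e-12)

  m <- matrix(rpois(900, 50), 30, 30)
  shifted <- background_correct(m + 20, percentile = 0.05)
  plain <- background_correct(m, percentile = 0.05)
  expect_equal(shifted, plain, tolerance = 1e-12)
})

test_that("expression binning is left-closed with configurable thresholds", {
  rec <- data.frame(total_intensity = c(0, 10, 20, 25, 40))
  b <- bin_cells_by_expression(rec, thresholds = c(10, 25))
  expect_equal(as.character(b$expression_bin),
               c("non", "low", "low", "high", "high"))
  expect_error(bin_cells_by_expression(rec, thresholds = c(25, 10)), "t1 < t2")
  expect_error(bin_cells_by_expression(rec, channel = "nope"), "no column")

  # default percentile thresholds produce all three bins
  set.seed(8)
  rec2 <- data.frame(total_intensity = c(rnorm(50, 10, 1), rnorm(50, 50, 2),
                                         rnorm(50, 120, 5)))
  b2 <- bin_cells_by_expression(rec2)
  expect_setequal(levels(b2$expression_bin), c("non", "low", "high"))

  # well-separated mixture: >=90% of cells fall in their true bin
  truth <- rep(c("non", "low", "high"), each = 50)
  b3 <- bin_cells_by_expression(rec2, thresholds = c(30, 85))
  expect_gte(mean(as.character(b3$expression_bin) == truth), 0.9)
})

test_that("multinucleation fraction counts cells with two or more nuclei", {
  cells <- matrix(rep(1:10, each = 10), 10, 10)
  nuc <- matrix(0L, 10, 10)
  for (k in 1:10) nuc[3, k] <- k          # one nucleus per cell
  expect_equal(multinucleation_fraction(cells, nuc), 0)
  nuc[7, 1] <- 11L; nuc[7, 2] <- 12L      # second nucleus in cells 1 and 2
  expect_equal(multinucleation_fraction(cells, nuc), 0.2)
  expect_warning(out <- multinucleation_fraction(matrix(0L, 5, 5), nuc[1:5, 1:5]),
                 "no cells")
  expect_true(is.na(out))

  # INCENP-like simulated field
  sim <- simulate_cell_field(n_cells = 20, binucleation_fraction = 0.4,
                             dim = c(160, 160), seed = 4)
  nucs <- segment_nuclei(sim$field)
  cl <- segment_cells(sim$field, nucs, merge_seed_distance = 5)
  expect_lt(abs(multinucleation_fraction(cl, nucs) - 0.4), 0.05)
})

test_that("RUSH transport index subtracts the non-release leak", {
  expect_equal(rush_transport_index(c(0.3, 0.3), c(0.3, 0.3))$index, 0)
  r <- rush_transport_index(rep(0.5, 10), rep(0.1, 10))
  expect_equal(r$index, 0.4)
  expect_equal(r$release_mean, 0.5)
  expect_error(rush_transport_index(numeric(0), 0.1), "non-empty")

  # a knockdown reducing release by a programmed factor shows up in the
  # normalized index within 10%
  leak <- 0.1
  ctrl <- simulate_cell_field(n_cells = 16, ratios = leak + 0.4, dim = c(128, 128),
                              seed = 10)
  kd <- simulate_cell_field(n_cells = 16, ratios = leak + 0.4 * 0.45,
                            dim = c(128, 128), seed = 11)
  nr <- simulate_cell_field(n_cells = 16, ratios = leak, dim = c(128, 128),
                            seed = 12)
  get_rec <- function(s) {
    per_cell_transport_ratio(s$field, s$cell_mask, s$nucleus_mask)
  }
  i_ctrl <- rush_transport_index(get_rec(ctrl), get_rec(nr))$index
  i_kd <- rush_transport_index(get_rec(kd), get_rec(nr))$index
  expect_lt(abs(i_kd / i_ctrl - 0.45), 0.1)
})

test_that("cell records write to CSV with their schema intact", {
  sim <- simulate_cell_field(n_cells = 4, seed = 5)
  rec <- per_cell_transport_ratio(sim$field, sim$cell_mask, sim$nucleus_mask)
  path <- tempfile(fileext = ".csv")
  write_cell_records(rec, path)
  back <- read.csv(path)
  expect_equal(back$transport_ratio, rec$transport_ratio)
  expect_equal(names(back), names(rec))
})
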