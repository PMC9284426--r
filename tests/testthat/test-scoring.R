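test_that("spot_ratio averages valid cells and guards low counts", {
  expect_equal(spot_ratio(c(0.2, 0.4), min_cells = 2)$xi, 0.3)
  low <- spot_ratio(rnorm(10, 0.5, 0.01), min_cells = 20)
  expect_true(is.na(low$xi))
  expect_equal(low$flags, "low_cell_count")
  expect_equal(low$n_cells, 10)
  empty <- spot_ratio(numeric(0), min_cells = 1)
  expect_true(is.na(empty$xi))
  # flagged cells (NA) are excluded before the min-cells check
  withNA <- spot_ratio(c(0.2, 0.4, NA, NA), min_cells = 2)
  expect_equal(withNA$xi, 0.3)
  expect_equal(withNA$n_cells, 2)
  expect_equal(spot_ratio(c(0.1, 0.1, 10), min_cells = 3,
                          statistic = "median")$xi, 0.1)
})

test_that("neighborhood windows truncate at edges and flag sparse windows", {
  lay <- tiny_layout(n_rows = 8, n_cols = 10)
  xi <- matrix(rnorm(80, 0.5, 0.05), 8, 10)
  expect_length(neighborhood_window(lay, 4, 5, xi)$values, 25)
  corner <- neighborhood_window(lay, 0, 0, xi, min_window = 9)
  expect_length(corner$values, 9)
  expect_equal(corner$flags, "")
  expect_equal(neighborhood_window(lay, 0, 0, xi, min_window = 12)$flags,
               "insufficient_window")
  expect_length(neighborhood_window(lay, 0, 4, xi)$values, 15)
  holey <- xi
  holey[3:7, 4:8] <- NA
  expect_equal(neighborhood_window(lay, 4, 5, holey)$flags,
               "insufficient_window")
})

test_that("transport score reproduces the hand-computed median/MAD oracle", {
  ts <- transport_score(19, 1:25)
  expect_identical(ts$X, 13)
  expect_identical(ts$mad, 6)
  expect_identical(ts$score, 1)

  # a spot equal to its window median scores exactly zero
  w <- c(0.31, 0.52, 0.47, 0.55, 0.62, 0.44, 0.50, 0.58, 0.41)
  expect_identical(transport_score(brute_median(w), w)$score, 0)

  # zero spread is flagged degenerate, never infinite
  deg <- transport_score(0.7, rep(0.5, 25))
  expect_true(is.na(deg$score))
  expect_equal(deg$flags, "degenerate_mad")
  expect_equal(deg$mad, 0)

  expect_equal(transport_score(NA, 1:25)$flags, "missing_xi")
})

test_that("transport score matches the brute-force oracle on random windows", {
  set.seed(42)
  for (i in 1:200) {
    w <- rnorm(25, 0.5, 0.1)
    xi <- rnorm(1, 0.5, 0.1)
    expect_identical(transport_score(xi, w)$score, brute_transport_score(xi, w))
  }
})

test_that("scores are invariant under affine rescaling of all ratios", {
  lay <- tiny_layout()
  set.seed(7)
  sr <- data.frame(row = lay$spots$row, col = lay$spots$col,
                   xi = rnorm(80, 0.5, 0.08), n_cells = 200)
  s1 <- score_plate(lay, sr)
  sr2 <- sr
  sr2$xi <- 3.7 * sr$xi + 0.21
  s2 <- score_plate(lay, sr2)
  expect_lt(max(abs(s1$score - s2$score), na.rm = TRUE), 1e-9)
})

test_that("score is strictly increasing in xi for a fixed window", {
  w <- rnorm(25, 0.5, 0.1)
  xs <- seq(0.1, 0.9, length.out = 20)
  sc <- vapply(xs, function(x) transport_score(x, w)$score, numeric(1))
  expect_true(all(diff(sc) > 0))
})

test_that("median/MAD resist a few corrupted window values", {
  set.seed(11)
  for (i in 1:50) {
    w <- rnorm(25, 0.5, 0.05)
    clean <- transport_score(0.5, w)
    wc <- w
    k <- sample(25, 4)
    wc[k] <- wc[k] * 10 * sample(c(-1, 1), 4, replace = TRUE)
    dirty <- transport_score(0.5, wc)
    # the window median stays within the clean values' range and the MAD
    # within a modest factor: 4 of 25 corruptions cannot break either
    expect_gte(dirty$X, min(w))
    expect_lte(dirty$X, max(w))
    expect_lt(dirty$mad / clean$mad, 4)
  }
})

test_that("score_plate is deterministic and respects the sign convention", {
  lay <- tiny_layout()
  set.seed(3)
  sr <- data.frame(row = lay$spots$row, col = lay$spots$col,
                   xi = rnorm(80, 0.5, 0.03), n_cells = 200)
  # transport inhibition at one spot: strongly negative score
  spiked <- sr
  spiked$xi[spiked$row == 4 & spiked$col == 5] <- 0.1
  sc <- score_plate(lay, spiked)
  expect_lt(sc$score[sc$row == 4 & sc$col == 5], -3)
  expect_identical(score_plate(lay, spiked), sc)

  # uniform plate: every scorable window degenerates (corner windows fall
  # below the minimum-window guard instead); no spot gets a numeric score
  uni <- sr
  uni$xi <- 0.5
  su <- score_plate(lay, uni)
  expect_true(all(su$flags %in% c("degenerate_mad", "insufficient_window")))
  expect_true(sum(su$flags == "degenerate_mad") > 0.9 * nrow(su))
  expect_true(all(is.na(su$score)))
})

test_that("plate QC applies the control criteria", {
  lay <- tiny_layout()
  set.seed(5)
  sr <- data.frame(row = lay$spots$row, col = lay$spots$col,
                   xi = rnorm(80, 0.5, 0.05), n_cells = 200)
  sc <- score_plate(lay, sr)
  # impose known control scores: strong positives, near-zero negatives
  sc$score[sc$control_role == "positive"] <- c(-4.1, -3.8)
  sc$score[sc$control_role == "negative"] <- c(0.08, -0.16)
  q <- plate_qc(sc, lay)
  expect_true(q$negative_ok)
  expect_true(q$positive_ok)
  expect_true(q$passed)

  # weak positive controls fail the plate
  sc$score[sc$control_role == "positive"] <- c(-0.5, -0.4)
  expect_false(plate_qc(sc, lay)$passed)

  # strict per-spot rule
  sc$score[sc$control_role == "positive"] <- c(-4.1, -3.8)
  sc$score[sc$control_role == "negative"] <- c(0.08, -0.7)
  expect_true(plate_qc(sc, lay, neg_rule = "median")$passed)
  expect_false(plate_qc(sc, lay, neg_rule = "all")$passed)

  # a missing control class fails with a reason
  no_pos <- sc[sc$control_role != "positive", ]
  qf <- plate_qc(no_pos, lay)
  expect_false(qf$passed)
  expect_true("no_positive_controls" %in% qf$reasons)

  # transfection criterion only evaluated when measured
  expect_false(plate_qc(sc, lay, transfection_fraction = 0.2)$passed)
  expect_true(plate_qc(sc, lay, transfection_fraction = 0.8)$passed)
})

test_that("replicate aggregation uses the median and the >=3 replicas rule", {
  df <- data.frame(sirna_id = "siA", background = "SEC23A",
                   replicate = 1:5, score = c(-2.0, -1.8, -1.7, -1.6, 0.1))
  agg <- aggregate_replicates(df)
  expect_equal(agg$median_score, -1.7)
  expect_equal(agg$n_replicates, 5L)
  expect_false(agg$excluded)

  two <- aggregate_replicates(df[1:2, ])
  expect_true(two$excluded)
  expect_true(is.na(two$median_score))
  expect_equal(two$reason, "insufficient_replicates")

  # duplicate spots within one replicate collapse first
  dup <- rbind(df, data.frame(sirna_id = "siA", background = "SEC23A",
                              replicate = 1, score = -1))
  agg2 <- aggregate_replicates(dup)
  expect_equal(agg2$median_score, median(c(median(c(-2, -1)), -1.8, -1.7, -1.6, 0.1)))
})

test_that("2^-ddCT fold changes match their closed form", {
  expect_equal(ddct_fold_change(20, 18, 20, 18), 1.0)
  expect_equal(ddct_fold_change(22, 18, 21, 18), 0.5)
  expect_equal(ddct_fold_change(21, 18, 22, 18), 2.0)
  expect_equal(ddct_fold_change(c(22, 21), 18, 21, 18), c(0.5, 1))
  expect_error(ddct_fold_change(NA, 18, 21, 18))
})
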