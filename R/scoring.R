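#' Mean per-spot transport ratio
#'
#' Averages the per-cell transport ratios measured on one siRNA spot into
#' the spot statistic `xi`. Flagged cells (missing ratio, e.g. zero total
#' intensity) are dropped; if fewer than `min_cells` valid cells remain the
#' spot is flagged `low_cell_count` and gets no `xi`.
#'
#' @param ratios Numeric vector of per-cell transport ratios (NA = flagged),
#'   or a data.frame with a `transport_ratio` column as produced by
#'   [per_cell_transport_ratio()].
#' @param min_cells Minimum number of valid cells for a usable spot.
#' @param statistic `"mean"` (default, the screen's per-spot statistic) or
#'   `"median"`.
#' @return A list with `xi` (NA when flagged), `n_cells`, `flags`.
#' @export
spot_ratio <- function(ratios, min_cells = 20, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  if (is.data.frame(ratios)) ratios <- ratios$transport_ratio
  ratios <- ratios[is.finite(ratios)]
  n <- length(ratios)
  if (n < min_cells) {
    return(list(xi = NA_real_, n_cells = n, flags = "low_cell_count"))
  }
  xi <- if (statistic == "mean") mean(ratios) else stats::median(ratios)
  list(xi = xi, n_cells = n, flags = "")
}

#' 5x5 neighborhood window of per-spot ratios
#'
#' Collects the `xi` values of the (2h+1) x (2h+1) grid window centered on a
#' spot (center included; 25 values for the default h = 2 on a full plate).
#' The window is truncated at plate edges and spots with missing `xi` are
#' omitted; when fewer than `min_window` values remain the window is flagged
#' `insufficient_window`.
#'
#' @param layout A `plate_layout`.
#' @param row,col 0-based coordinates of the center spot.
#' @param xi A `n_rows` x `n_cols` matrix of per-spot ratios (NA = missing),
#'   as built by [xi_matrix()].
#' @param half_width Window half-width (2 gives the 5x5 window).
#' @param min_window Minimum number of usable values.
#' @return A list with `values` (numeric) and `flags`.
#' @export
neighborhood_window <- function(layout, row, col, xi, half_width = 2,
                                min_window = 12) {
  stopifnot(row >= 0, row < layout$n_rows, col >= 0, col < layout$n_cols)
  rows <- max(0, row - half_width):min(layout$n_rows - 1, row + half_width)
  cols <- max(0, col - half_width):min(layout$n_cols - 1, col + half_width)
  vals <- as.vector(xi[rows + 1L, cols + 1L])
  vals <- vals[is.finite(vals)]
  flags <- if (length(vals) < min_window) "insufficient_window" else ""
  list(values = vals, flags = flags)
}

#' Arrange per-spot ratios into a plate matrix
#'
#' @param layout A `plate_layout`.
#' @param spot_ratios A data.frame with columns `row`, `col`, `xi`.
#' @return A `n_rows` x `n_cols` numeric matrix (NA where no usable spot).
#' @export
xi_matrix <- function(layout, spot_ratios) {
  m <- matrix(NA_real_, layout$n_rows, layout$n_cols)
  m[cbind(spot_ratios$row + 1L, spot_ratios$col + 1L)] <- spot_ratios$xi
  m
}

#' Spatially normalized transport score
#'
#' The screen statistic: `score = (xi - X) / MAD`, where `X` is the median
#' of the neighborhood window values (the 5x5 matrix of per-spot transport
#' ratios around the spot of interest, center included) and `MAD` is the
#' median absolute deviation of the same window, used without a consistency
#' constant. Negative scores indicate transport inhibition, positive scores
#' acceleration. A window with zero MAD cannot be scored and is flagged
#' `degenerate_mad` (the score is NA, never infinite).
#'
#' @param xi Per-spot mean transport ratio.
#' @param window_values Numeric vector of window ratios (center included).
#' @return List with `X`, `mad`, `score`, `flags`.
#' @export
transport_score <- function(xi, window_values) {
  window_values <- as.numeric(window_values[is.finite(window_values)])
  if (!is.finite(xi) || length(window_values) == 0) {
    return(list(X = NA_real_, mad = NA_real_, score = NA_real_, flags = "missing_xi"))
  }
  X <- stats::median(window_values)
  mad <- stats::median(abs(window_values - X))
  if (mad == 0) {
    return(list(X = X, mad = 0, score = NA_real_, flags = "degenerate_mad"))
  }
  list(X = X, mad = mad, score = (xi - X) / mad, flags = "")
}

#' Score every spot of a plate
#'
#' Joins per-spot ratios onto the layout, builds each spot's 5x5
#' neighborhood window and computes the normalized transport score. Spots
#' whose window is truncated below `min_window` usable values, or whose
#' window MAD is zero, carry an NA score plus a flag; everything else gets a
#' deterministic score.
#'
#' @param layout A `plate_layout`.
#' @param spot_ratios Data.frame with columns `row`, `col`, `xi`, `n_cells`
#'   (e.g. from [plate_spot_ratios()]); rows with NA `xi` are treated as
#'   missing spots.
#' @param half_width,min_window See [neighborhood_window()].
#' @param include_controls Should control spots contribute to neighborhood
#'   windows? Default TRUE (the window median is robust to sparse control
#'   outliers).
#' @return Data.frame of `SpotScore` rows: layout columns plus `xi`,
#'   `n_cells`, `X`, `mad`, `score`, `flags`.
#' @export
score_plate <- function(layout, spot_ratios, half_width = 2, min_window = 12,
                        include_controls = TRUE) {
  stopifnot(inherits(layout, "plate_layout"))
  xi <- xi_matrix(layout, spot_ratios)
  xi_win <- xi
  if (!include_controls) {
    ctrl <- layout$spots[layout$spots$control_role != "sample", ]
    xi_win[cbind(ctrl$row + 1L, ctrl$col + 1L)] <- NA_real_
  }
  ncell <- matrix(NA_integer_, layout$n_rows, layout$n_cols)
  if ("n_cells" %in% names(spot_ratios)) {
    ncell[cbind(spot_ratios$row + 1L, spot_ratios$col + 1L)] <- spot_ratios$n_cells
  }
  out <- layout$spots
  out$chamber_id <- layout$chamber_id
  n <- nrow(out)
  out$xi <- xi[cbind(out$row + 1L, out$col + 1L)]
  out$n_cells <- ncell[cbind(out$row + 1L, out$col + 1L)]
  out$X <- out$mad <- out$score <- rep(NA_real_, n)
  out$flags <- character(n)
  for (i in seq_len(n)) {
    if (!is.finite(out$xi[i])) {
      out$flags[i] <- "missing_xi"
      next
    }
    w <- neighborhood_window(layout, out$row[i], out$col[i], xi_win,
                             half_width = half_width, min_window = min_window)
    if (w$flags != "") {
      out$flags[i] <- w$flags
      next
    }
    ts <- transport_score(out$xi[i], w$values)
    out$X[i] <- ts$X
    out$mad[i] <- ts$mad
    out$score[i] <- ts$score
    out$flags[i] <- ts$flags
  }
  out
}

#' Per-spot ratios for a whole plate from a per-cell table
#'
#' @param cells Data.frame with columns `row`, `col`, `transport_ratio`
#'   (one row per cell), e.g. from [simulate_plate()] or the image pipeline.
#' @param min_cells Minimum valid cells per spot.
#' @param statistic Per-spot statistic, see [spot_ratio()].
#' @return Data.frame with `row`, `col`, `xi`, `n_cells`, `flags`.
#' @export
plate_spot_ratios <- function(cells, min_cells = 20, statistic = "mean") {
  key <- interaction(cells$row, cells$col, drop = TRUE)
  parts <- split(cells$transport_ratio, key)
  coords <- do.call(rbind, strsplit(names(parts), ".", fixed = TRUE))
  res <- lapply(parts, spot_ratio, min_cells = min_cells, statistic = statistic)
  data.frame(row = as.integer(coords[, 1]), col = as.integer(coords[, 2]),
             xi = vapply(res, `[[`, numeric(1), "xi"),
             n_cells = vapply(res, `[[`, integer(1), "n_cells"),
             flags = vapply(res, `[[`, character(1), "flags"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Plate quality control from control spots
#'
#' A plate passes when (i) its positive controls show strong transport
#' inhibition: median positive-control score <= `pos_max`; (ii) its negative
#' controls sit close to zero: by default the median of the negative-control
#' scores satisfies |median| <= `neg_abs_max` (`neg_rule = "all"` instead
#' requires every negative spot within the band); and (iii) when a
#' transfection-QC multinucleation fraction is supplied, it reaches
#' `min_transfection`. A missing control class fails the plate outright.
#' Criteria without data (e.g. no multinucleation measurement) are recorded
#' as not assessed and do not fail the plate.
#'
#' @param scores Output of [score_plate()].
#' @param layout The plate's `plate_layout`.
#' @param pos_max Maximum allowed median positive-control score (default
#'   -1.5, the screen's strong-inhibition threshold).
#' @param neg_abs_max Band around zero for negative-control scores.
#' @param neg_rule `"median"` or `"all"`.
#' @param transfection_fraction Optional multinucleation fraction measured on
#'   the transfection-QC (INCENP) spots.
#' @param min_transfection Minimum multinucleation fraction.
#' @return A `plate_qc_report` list: `chamber_id`, `positive_control_scores`,
#'   `negative_control_scores`, `transfection_fraction`, per-criterion
#'   verdicts, `passed`, `reasons`.
#' @export
plate_qc <- function(scores, layout, pos_max = -1.5, neg_abs_max = 0.5,
                     neg_rule = c("median", "all"),
                     transfection_fraction = NA_real_, min_transfection = 0.5) {
  neg_rule <- match.arg(neg_rule)
  pos <- scores$score[scores$control_role == "positive"]
  neg <- scores$score[scores$control_role == "negative"]
  pos <- pos[is.finite(pos)]
  neg <- neg[is.finite(neg)]
  reasons <- character(0)

  if (length(pos) == 0) {
    pos_ok <- FALSE
    reasons <- c(reasons, "no_positive_controls")
  } else if (stats::median(pos) > pos_max) {
    pos_ok <- FALSE
    reasons <- c(reasons, sprintf("positive_controls_weak(median=%.2f)", stats::median(pos)))
  } else pos_ok <- TRUE

  if (length(neg) == 0) {
    neg_ok <- FALSE
    reasons <- c(reasons, "no_negative_controls")
  } else {
    dev <- if (neg_rule == "median") abs(stats::median(neg)) else max(abs(neg))
    if (dev > neg_abs_max) {
      neg_ok <- FALSE
      reasons <- c(reasons, sprintf("negative_controls_off_zero(%.2f)", dev))
    } else neg_ok <- TRUE
  }

  if (is.na(transfection_fraction)) {
    transfection_ok <- NA
  } else if (transfection_fraction < min_transfection) {
    transfection_ok <- FALSE
    reasons <- c(reasons, sprintf("low_transfection(%.2f)", transfection_fraction))
  } else transfection_ok <- TRUE

  passed <- pos_ok && neg_ok && !isFALSE(transfection_ok)
  structure(
    list(chamber_id = scores$chamber_id[1], background = layout$background,
         positive_control_scores = pos, negative_control_scores = neg,
         transfection_fraction = transfection_fraction,
         positive_ok = pos_ok, negative_ok = neg_ok,
         transfection_ok = transfection_ok,
         passed = passed, reasons = reasons),
    class = "plate_qc_report")
}

#' @export
print.plate_qc_report <- function(x, ...) {
  cat("plate_qc_report ", x$chamber_id, ": ",
      if (x$passed) "PASSED" else "FAILED", "\n", sep = "")
  cat("  median positive-control score:",
      round(stats::median(x$positive_control_scores), 3), "\n")
  cat("  median negative-control score:",
      round(stats::median(x$negative_control_scores), 3), "\n")
  if (length(x$reasons)) cat("  reasons:", paste(x$reasons, collapse = "; "), "\n")
  invisible(x)
}

#' Aggregate replicate transport scores per condition
#'
#' A condition is one (siRNA, background) pair. Its per-replicate scores are
#' collapsed to the median; conditions with fewer than `min_replicates`
#' biological replicates are excluded (the screen rule: at least three
#' biological replicas, then the median).
#'
#' @param replicate_scores Data.frame with columns `sirna_id`, `background`,
#'   `replicate`, `score`. Multiple spots of the same condition within one
#'   replicate are first collapsed to their median.
#' @param min_replicates Minimum biological replicates.
#' @return Data.frame of `GeneScore` rows (`sirna_id`, `background`,
#'   `median_score`, `n_replicates`, `excluded`, `reason`).
#' @export
aggregate_replicates <- function(replicate_scores, min_replicates = 3) {
  stopifnot(all(c("sirna_id", "background", "replicate", "score") %in%
                  names(replicate_scores)))
  df <- replicate_scores[is.finite(replicate_scores$score), ]
  # collapse within-replicate duplicate spots first
  key_rep <- paste(df$sirna_id, df$background, df$replicate, sep = "\r")
  per_rep <- vapply(split(df$score, key_rep), stats::median, numeric(1))
  parts <- do.call(rbind, strsplit(names(per_rep), "\r", fixed = TRUE))
  agg_key <- paste(parts[, 1], parts[, 2], sep = "\r")
  med <- vapply(split(per_rep, agg_key), stats::median, numeric(1))
  nrep <- vapply(split(per_rep, agg_key), length, integer(1))
  cond <- do.call(rbind, strsplit(names(med), "\r", fixed = TRUE))
  out <- data.frame(sirna_id = cond[, 1], background = cond[, 2],
                    median_score = unname(med), n_replicates = unname(nrep),
                    stringsAsFactors = FALSE)
  out$excluded <- out$n_replicates < min_replicates
  out$median_score[out$excluded] <- NA_real_
  out$reason <- ifelse(out$excluded, "insufficient_replicates", "")
  out[order(out$background, out$sirna_id), ]
}

#' Relative expression by the 2^-ddCT method
#'
#' Fold change of a target transcript in a treated sample relative to a
#' control sample, each normalized to a housekeeping gene (e.g. GAPDH):
#' `fold = 2^-((ct_target_treated - ct_hk_treated) -
#' (ct_target_control - ct_hk_control))`.
#'
#' @param ct_target_treated,ct_hk_treated,ct_target_control,ct_hk_control
#'   Threshold-cycle values; vectors recycle element-wise.
#' @return Fold change(s).
#' @export
ddct_fold_change <- function(ct_target_treated, ct_hk_treated,
                             ct_target_control, ct_hk_control) {
  stopifnot(all(is.finite(c(ct_target_treated, ct_hk_treated,
                            ct_target_control, ct_hk_control))))
  ddct <- (ct_target_treated - ct_hk_treated) -
    (ct_target_control - ct_hk_control)
  2^(-ddct)
}
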