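#' Classify a transport score as strong effector
#'
#' Scores at or below the inhibition threshold (default -1.5, set on the
#' screen's positive controls) are strong transport inhibitors; by symmetry
#' scores at or above +1.5 are transport accelerators; anything in between
#' is no strong effect. Missing scores classify as `none`.
#'
#' @param score Numeric vector of transport scores.
#' @param inhibit_threshold,accelerate_threshold Class boundaries.
#' @return Character vector in `{"inhibitor", "accelerator", "none"}`.
#' @export
classify_effect <- function(score, inhibit_threshold = -1.5,
                            accelerate_threshold = 1.5) {
  out <- rep("none", length(score))
  out[!is.na(score) & score <= inhibit_threshold] <- "inhibitor"
  out[!is.na(score) & score >= accelerate_threshold] <- "accelerator"
  out
}

#' Vectorized synergy predicate
#'
#' The hit rule shared by [call_synergy()]: a (gene, background) pair is a
#' hit when the double-knockdown score is a strong effector and its
#' deviation from the additive expectation of the single knockdowns
#' exceeds `min_difference` score units.
#'
#' @inheritParams call_synergy
#' @return Logical vector (`NA` scores give `FALSE`).
#' @export
synergy_is_hit <- function(single_gene, single_background, double,
                           min_difference = 1.0,
                           inhibit_threshold = -1.5,
                           accelerate_threshold = 1.5) {
  effect <- classify_effect(double, inhibit_threshold, accelerate_threshold)
  difference <- double - (single_gene + single_background)
  out <- effect != "none" & abs(difference) > min_difference
  out[is.na(out)] <- FALSE
  out
}

#' Synergy call for one double-knockdown condition
#'
#' Compares the double-knockdown transport score against the additive
#' expectation (sum of the two single-knockdown scores). A condition is a
#' hit when the double knockdown is itself a strong effector
#' (|score| >= 1.5 by default) and the deviation from additivity
#' `double - (single_gene + single_background)` exceeds `min_difference`
#' transport-score units (in absolute value by default; `mode = "signed"`
#' requires the deviation to exceed the margin in the direction of the
#' double effect).
#'
#' @param single_gene Median transport score of the gene knockdown alone
#'   (control background).
#' @param single_background Median score of the background (SEC23A/SEC23B)
#'   knockdown alone.
#' @param double Median score of the double knockdown.
#' @param min_difference Additivity margin in score units.
#' @param mode `"absolute"` or `"signed"`.
#' @param inhibit_threshold,accelerate_threshold Passed to
#'   [classify_effect()].
#' @param gene,background Optional identifiers carried into the call.
#' @return A one-row data.frame (`HitCall`): scores, `additive_expectation`,
#'   `difference`, `effect_class`, `is_hit`, `reason`.
#' @export
call_synergy <- function(single_gene, single_background, double,
                         min_difference = 1.0, mode = c("absolute", "signed"),
                         inhibit_threshold = -1.5, accelerate_threshold = 1.5,
                         gene = NA_character_, background = NA_character_) {
  mode <- match.arg(mode)
  if (anyNA(c(single_gene, single_background, double))) {
    return(data.frame(gene = gene, background = background,
                      single_gene_score = single_gene,
                      single_background_score = single_background,
                      double_score = double,
                      additive_expectation = NA_real_, difference = NA_real_,
                      effect_class = "none", is_hit = FALSE,
                      reason = "missing_score", stringsAsFactors = FALSE))
  }
  expectation <- single_gene + single_background
  difference <- double - expectation
  effect <- classify_effect(double, inhibit_threshold, accelerate_threshold)
  is_hit <- if (mode == "absolute") {
    synergy_is_hit(single_gene, single_background, double, min_difference,
                   inhibit_threshold, accelerate_threshold)
  } else {
    (effect == "inhibitor" && difference < -min_difference) ||
      (effect == "accelerator" && difference > min_difference)
  }
  reason <- if (is_hit) "" else if (effect == "none") "weak_double_score" else
    "additive"
  data.frame(gene = gene, background = background,
             single_gene_score = single_gene,
             single_background_score = single_background,
             double_score = double, additive_expectation = expectation,
             difference = difference, effect_class = effect, is_hit = is_hit,
             reason = reason, stringsAsFactors = FALSE)
}

#' Rank synergy hits
#'
#' Hits first, ordered by |double score| descending; ties broken by
#' |difference| descending, then gene id lexicographically.
#'
#' @param calls Data.frame of `HitCall` rows.
#' @param hits_only Keep only `is_hit` rows (default TRUE).
#' @return The ordered table with a `rank` column.
#' @export
rank_hits <- function(calls, hits_only = TRUE) {
  if (nrow(calls) == 0) {
    calls$rank <- integer(0)
    return(calls)
  }
  if (hits_only) calls <- calls[calls$is_hit %in% TRUE, , drop = FALSE]
  if (nrow(calls) == 0) {
    calls$rank <- integer(0)
    return(calls)
  }
  ord <- order(-abs(calls$double_score), -abs(calls$difference), calls$gene)
  calls <- calls[ord, , drop = FALSE]
  calls$rank <- seq_len(nrow(calls))
  rownames(calls) <- NULL
  calls
}

#' Synergy calls for a whole screen
#'
#' Builds one `HitCall` per (sample siRNA, background) pair from aggregated
#' condition scores: the double score is the siRNA's score on the background
#' chamber, the single-gene score its score on the control background, and
#' the single-background score that of the siRNA targeting the background
#' gene (e.g. `siSEC23A`) on the control background.
#'
#' @param gene_scores Output of [aggregate_replicates()].
#' @param backgrounds Backgrounds to call against.
#' @param background_sirna Named map background -> siRNA id measuring its
#'   single knockdown.
#' @param sample_sirnas Optional character vector restricting candidates
#'   (e.g. the library's sample siRNAs); defaults to every siRNA scored on a
#'   background chamber other than the background-targeting siRNAs.
#' @param ... Passed to [call_synergy()].
#' @return Data.frame of `HitCall` rows (unranked; see [rank_hits()]).
#' @export
call_screen_hits <- function(gene_scores,
                             backgrounds = c("SEC23A", "SEC23B"),
                             background_sirna = c(SEC23A = "siSEC23A",
                                                  SEC23B = "siSEC23B"),
                             sample_sirnas = NULL, ...) {
  gs <- gene_scores[!gene_scores$excluded, ]
  lookup <- function(sirna, bg) {
    v <- gs$median_score[gs$sirna_id == sirna & gs$background == bg]
    if (length(v) == 1) v else NA_real_
  }
  calls <- list()
  for (bg in backgrounds) {
    sb <- lookup(background_sirna[[bg]], "control")
    cand <- unique(gs$sirna_id[gs$background == bg])
    cand <- setdiff(cand, unname(background_sirna))
    if (!is.null(sample_sirnas)) cand <- intersect(cand, sample_sirnas)
    for (g in cand) {
      calls[[paste(g, bg)]] <- call_synergy(
        single_gene = lookup(g, "control"), single_background = sb,
        double = lookup(g, bg), gene = g, background = bg, ...)
    }
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}
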