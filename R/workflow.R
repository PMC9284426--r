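#' Simulate the plates of a full replicated screen
#'
#' One biological replicate = the chamber set re-run under each
#' co-transfection background (control, SEC23A, SEC23B). Per plate this
#' simulates the per-cell table and collapses it to per-spot ratios. Plate
#' seeds derive deterministically from `seed` and the plate's replicate /
#' background / chamber indices.
#'
#' @param layouts Chamber layouts (control background), e.g. from
#'   [design_screen_layouts()].
#' @param truth A [screen_truth()].
#' @param n_replicates Biological replicates (the screen used five).
#' @param backgrounds Backgrounds each replicate is run under.
#' @param seed Integer base seed.
#' @param min_cells Minimum valid cells per spot.
#' @return List of plates, each `list(layout, replicate, spot_ratios)`.
#' @export
simulate_screen <- function(layouts, truth, n_replicates = 5,
                            backgrounds = c("control", "SEC23A", "SEC23B"),
                            seed = 1, min_cells = 20) {
  plates <- list()
  for (r in seq_len(n_replicates)) {
    for (bi in seq_along(backgrounds)) {
      for (ci in seq_along(layouts)) {
        lay <- with_background(layouts[[ci]], backgrounds[bi])
        plate_seed <- (seed * 97L + r * 1009L + bi * 131L + ci * 17L) %% 2147483629L
        cells <- simulate_plate(lay, truth, seed = plate_seed)
        plates[[length(plates) + 1]] <- list(
          layout = lay, replicate = r,
          spot_ratios = plate_spot_ratios(cells, min_cells = min_cells))
      }
    }
  }
  plates
}

#' Analyze a replicated screen in memory
#'
#' The full scoring path: per-plate 5x5 median/MAD transport scores, plate
#' QC on positive/negative controls, exclusion of failing plates,
#' replicate aggregation (median over >= `min_replicates` replicas), and
#' synergy hit calling against the additive expectation of the single
#' knockdowns.
#'
#' @param plates List of `list(layout, replicate, spot_ratios)` (see
#'   [simulate_screen()]), where `spot_ratios` has columns `row`, `col`,
#'   `xi`, `n_cells`.
#' @param qc Named list of [plate_qc()] arguments (e.g.
#'   `list(pos_max = -1.5, neg_abs_max = 0.5)`).
#' @param min_replicates Replicate rule (default 3).
#' @param min_difference,inhibit_threshold,accelerate_threshold Hit-calling
#'   parameters, see [call_synergy()].
#' @param include_controls Include control spots in scoring windows
#'   (default FALSE here: control spots carry engineered effects that
#'   differ between co-transfection backgrounds, so leaving them in the
#'   windows distorts the common score scale that single- and
#'   double-knockdown plates must share).
#' @return List with `spot_scores` (all plates), `qc_reports`,
#'   `excluded_plates`, `gene_scores`, `hit_calls`, `hits` (ranked),
#'   `log` (data.frame of exclusion events).
#' @export
analyze_screen <- function(plates, qc = list(), min_replicates = 3,
                           min_difference = 1.0, inhibit_threshold = -1.5,
                           accelerate_threshold = 1.5,
                           include_controls = FALSE) {
  if (length(plates) == 0) stop("no plates to analyze")
  scores_list <- list()
  qc_reports <- list()
  log <- list()
  keep <- list()
  for (p in plates) {
    sc <- score_plate(p$layout, p$spot_ratios,
                      include_controls = include_controls)
    sc$replicate <- p$replicate
    scores_list[[length(scores_list) + 1]] <- sc
    rep_qc <- do.call(plate_qc, c(list(scores = sc, layout = p$layout), qc))
    qc_reports[[paste(p$layout$chamber_id, p$replicate, sep = "_r")]] <- rep_qc
    if (rep_qc$passed) {
      keep[[length(keep) + 1]] <- sc
    } else {
      log[[length(log) + 1]] <- data.frame(
        event = "plate_excluded", chamber_id = p$layout$chamber_id,
        replicate = p$replicate,
        reason = paste(rep_qc$reasons, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  spot_scores <- do.call(rbind, scores_list)
  if (length(keep) == 0) {
    stop("no plates passed QC; screen cannot be aggregated")
  }
  kept <- do.call(rbind, keep)
  usable <- kept[is.finite(kept$score), ]
  replicate_scores <- data.frame(sirna_id = usable$sirna_id,
                                 background = usable$background,
                                 replicate = usable$replicate,
                                 score = usable$score,
                                 stringsAsFactors = FALSE)
  gene_scores <- aggregate_replicates(replicate_scores,
                                      min_replicates = min_replicates)
  excl <- gene_scores[gene_scores$excluded, ]
  if (nrow(excl) > 0) {
    log[[length(log) + 1]] <- data.frame(
      event = "condition_excluded", chamber_id = NA, replicate = NA,
      reason = paste0(excl$sirna_id, "|", excl$background, ":", excl$reason,
                      collapse = ";"),
      stringsAsFactors = FALSE)
  }
  sample_ids <- unique(kept$sirna_id[kept$control_role == "sample"])
  sample_ids <- setdiff(sample_ids, c("siSEC23A", "siSEC23B"))
  hit_calls <- call_screen_hits(gene_scores, sample_sirnas = sample_ids,
                                min_difference = min_difference,
                                inhibit_threshold = inhibit_threshold,
                                accelerate_threshold = accelerate_threshold)
  list(spot_scores = spot_scores, qc_reports = qc_reports,
       excluded_plates = do.call(rbind, log),
       gene_scores = gene_scores, hit_calls = hit_calls,
       hits = rank_hits(hit_calls),
       log = if (length(log)) do.call(rbind, log) else
         data.frame(event = character(0), chamber_id = character(0),
                    replicate = integer(0), reason = character(0)))
}

#' Run the screen pipeline end to end and write all outputs
#'
#' Orchestrates quantify -> score -> QC -> aggregate -> hits. The config is
#' serialized verbatim into the output directory together with the seed and
#' (for simulated screens) the ground truth, so every run regenerates from
#' its own output directory. Reruns with identical config and seed produce
#' byte-identical tables.
#'
#' @param config A list (or path to a JSON file) with entries:
#'   \describe{
#'     \item{out_dir}{Output directory (required).}
#'     \item{seed}{Integer seed (default 1).}
#'     \item{layouts}{List of `plate_layout` objects or layout file paths;
#'       default [design_screen_layouts()].}
#'     \item{truth}{A `screen_truth`, a truth JSON path, or a list of
#'       [screen_truth()] arguments; when absent, `ratio_files` must supply
#'       measured per-spot ratios.}
#'     \item{ratio_files}{Data.frame with `path`, `chamber_index`,
#'       `background`, `replicate`: per-spot ratio CSVs (`row,col,xi,n_cells`).}
#'     \item{n_replicates}{Simulated replicates (default 5).}
#'     \item{qc}{List of [plate_qc()] arguments.}
#'     \item{min_replicates, min_difference}{Aggregation / hit parameters.}
#'   }
#' @return Invisibly, the [analyze_screen()] result plus `out_dir`.
#' @export
run_screen <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  seed <- config$seed %||% 1L
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  layouts <- config$layouts %||% design_screen_layouts()
  layouts <- lapply(layouts, function(l) {
    if (is.character(l)) load_layout(l) else l
  })

  if (!is.null(config$truth)) {
    truth <- config$truth
    if (is.character(truth)) truth <- read_truth(truth)
    if (!inherits(truth, "screen_truth")) truth <- do.call(screen_truth, truth)
    plates <- simulate_screen(layouts, truth,
                              n_replicates = config$n_replicates %||% 5,
                              seed = seed)
    write_truth(truth, file.path(config$out_dir, "truth.json"))
  } else if (!is.null(config$ratio_files)) {
    rf <- as.data.frame(config$ratio_files)
    missing <- !file.exists(rf$path)
    if (any(missing)) stop("missing ratio files: ",
                           paste(rf$path[missing], collapse = ", "))
    plates <- lapply(seq_len(nrow(rf)), function(i) {
      lay <- with_background(layouts[[rf$chamber_index[i]]], rf$background[i])
      list(layout = lay, replicate = rf$replicate[i],
           spot_ratios = utils::read.csv(rf$path[i]))
    })
  } else {
    stop("config must provide either 'truth' (simulation) or 'ratio_files'")
  }

  res <- analyze_screen(plates, qc = config$qc %||% list(),
                        min_replicates = config$min_replicates %||% 3,
                        min_difference = config$min_difference %||% 1.0)

  out <- config$out_dir
  utils::write.csv(res$spot_scores, file.path(out, "spot_scores.csv"),
                   row.names = FALSE)
  utils::write.csv(res$gene_scores, file.path(out, "gene_scores.csv"),
                   row.names = FALSE)
  utils::write.csv(res$hit_calls, file.path(out, "hit_calls.csv"),
                   row.names = FALSE)
  utils::write.csv(res$hits, file.path(out, "hits.csv"), row.names = FALSE)
  qc_json <- lapply(res$qc_reports, unclass)
  jsonlite::write_json(qc_json, file.path(out, "qc_reports.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(out, "log.jsonl"), open = "wt")
  if (nrow(res$log) > 0) {
    for (i in seq_len(nrow(res$log))) {
      writeLines(jsonlite::toJSON(as.list(res$log[i, ]), auto_unbox = TRUE), con)
    }
  }
  close(con)
  manifest <- list(seed = seed,
                   n_plates = length(plates),
                   n_hits = sum(res$hit_calls$is_hit, na.rm = TRUE),
                   config = config[setdiff(names(config), c("layouts", "truth"))])
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(res, list(out_dir = out)))
}

#' Run an imaging subpipeline over conditions
#'
#' Applies one of the imaging pipelines to named conditions and enforces
#' the per-condition minimum-cell guards (100 cells for 3D puncta, 50 for
#' focal adhesions); under-powered conditions are flagged, never silently
#' summarized.
#'
#' @param config A list with `conditions`, a named list where each entry
#'   depends on `mode`:
#'   \describe{
#'     \item{spots3d}{`list(stacks = list of volume_stack, cells = optional
#'       list of cell masks, min_seed_intensity = numeric)`.}
#'     \item{adhesions}{`list(stacks = list of volume_stack, nuclei = list
#'       of nucleus masks or counts)`.}
#'     \item{rush}{`list(release = CellRecords, nonrelease = CellRecords)`.}
#'   }
#'   plus optional `out_dir` and guard overrides `min_cells`.
#' @param mode One of `"spots3d"`, `"adhesions"`, `"rush"`.
#' @return List with `per_condition` (data.frame) and mode-specific
#'   per-image/per-cell tables.
#' @export
run_imaging <- function(config, mode = c("spots3d", "adhesions", "rush")) {
  mode <- match.arg(mode)
  conds <- config$conditions
  if (is.null(conds) || length(conds) == 0) {
    stop("config$conditions is empty: nothing to quantify")
  }
  per_condition <- list()
  detail <- list()
  for (nm in names(conds)) {
    cond <- conds[[nm]]
    if (mode == "spots3d") {
      min_cells <- config$min_cells %||% 100
      tabs <- list()
      for (i in seq_along(cond$stacks)) {
        cs <- count_spots(cond$stacks[[i]],
                          min_seed_intensity = cond$min_seed_intensity,
                          min_cluster_volume = cond$min_cluster_volume %||% 300)
        cells <- if (!is.null(cond$cells)) cond$cells[[i]] else {
          d <- dim(.stack_channel(cond$stacks[[i]], "structure"))
          matrix(1L, d[1], d[2])
        }
        st <- per_cell_spot_stats(cs$labels, cells, cond$stacks[[i]])
        tabs[[i]] <- st$per_cell
      }
      s <- condition_spot_summary(tabs, min_cells = min_cells)
      per_condition[[nm]] <- data.frame(condition = nm, n_cells = s$n_cells,
                                        mean_count = s$mean_count,
                                        mean_spot_intensity = s$mean_spot_intensity,
                                        sufficient = s$sufficient,
                                        flags = s$flags, stringsAsFactors = FALSE)
      detail[[nm]] <- do.call(rbind, tabs)
    } else if (mode == "adhesions") {
      min_cells <- config$min_cells %||% 50
      rows <- list()
      for (i in seq_along(cond$stacks)) {
        seg <- fa_segment(cond$stacks[[i]])
        rows[[i]] <- fa_stats(seg$labels, cond$nuclei[[i]], seg$projection)
      }
      fa <- do.call(rbind, rows)
      s <- condition_fa_summary(fa, min_cells = min_cells)
      per_condition[[nm]] <- data.frame(condition = nm, n_cells = s$n_cells,
                                        mean_fa_area_per_cell = s$mean_fa_area_per_cell,
                                        mean_fa_size = s$mean_fa_size,
                                        sufficient = s$sufficient,
                                        flags = s$flags, stringsAsFactors = FALSE)
      detail[[nm]] <- fa
    } else {
      idx <- rush_transport_index(cond$release, cond$nonrelease)
      per_condition[[nm]] <- data.frame(condition = nm,
                                        transport_index = idx$index,
                                        release_mean = idx$release_mean,
                                        leak_mean = idx$leak_mean,
                                        n_cells = idx$n_release,
                                        sufficient = TRUE, flags = "",
                                        stringsAsFactors = FALSE)
      detail[[nm]] <- idx
    }
  }
  per_condition <- do.call(rbind, per_condition)
  rownames(per_condition) <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(per_condition,
                     file.path(config$out_dir, paste0(mode, "_conditions.csv")),
                     row.names = FALSE)
  }
  list(per_condition = per_condition, detail = detail)
}
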