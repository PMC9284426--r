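#' Spotted-chamber plate layout
#'
#' A `plate_layout` describes one spotted Lab-Tek-style chamber: the spot
#' grid geometry, the siRNA sitting on every spot, the control role of each
#' spot, and the chamber-level co-transfection background (the siRNA the
#' whole chamber was reverse-transfected with in suspension, e.g. SEC23A,
#' SEC23B or a non-targeting control). The background is a chamber-level
#' property and is denormalized onto every spot.
#'
#' Grid coordinates are 0-based and row-major throughout the package and in
#' all layout files.
#'
#' @param n_rows,n_cols Grid dimensions; `n_rows * n_cols` must equal the
#'   number of spots.
#' @param spots A data.frame with columns `row`, `col`, `sirna_id`,
#'   `target_gene`, `control_role`. `control_role` must be one of
#'   `"positive"`, `"negative"`, `"transfection_qc"`, `"sample"`.
#'   `target_gene` may be `NA` for non-targeting controls.
#' @param chamber_id Identifier for the chamber.
#' @param background Chamber-level background knockdown, one of
#'   `"SEC23A"`, `"SEC23B"`, `"control"`.
#' @return An object of class `plate_layout`.
#' @export
plate_layout <- function(n_rows, n_cols, spots, chamber_id, background = "control") {
  stopifnot(is.data.frame(spots))
  required <- c("row", "col", "sirna_id", "target_gene", "control_role")
  missing_cols <- setdiff(required, names(spots))
  if (length(missing_cols) > 0) {
    stop("layout is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  background <- match.arg(background, c("SEC23A", "SEC23B", "control"))
  spots <- spots[required]
  spots$row <- as.integer(spots$row)
  spots$col <- as.integer(spots$col)
  spots$sirna_id <- as.character(spots$sirna_id)
  spots$target_gene <- as.character(spots$target_gene)
  spots$control_role <- as.character(spots$control_role)

  if (nrow(spots) != n_rows * n_cols) {
    stop("n_rows * n_cols (", n_rows * n_cols, ") does not match number of spots (",
         nrow(spots), ")")
  }
  if (any(spots$row < 0L) || any(spots$row >= n_rows) ||
      any(spots$col < 0L) || any(spots$col >= n_cols)) {
    stop("spot coordinates out of range for a ", n_rows, "x", n_cols,
         " grid (coordinates are 0-based)")
  }
  key <- paste(spots$row, spots$col)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate spot coordinates (row col): ", dup)
  }
  bad_role <- setdiff(unique(spots$control_role),
                      c("positive", "negative", "transfection_qc", "sample"))
  if (length(bad_role) > 0) {
    stop("unknown control_role: ", paste(bad_role, collapse = ", "))
  }
  spots <- spots[order(spots$row, spots$col), , drop = FALSE]
  rownames(spots) <- NULL
  spots$background <- background

  structure(
    list(chamber_id = as.character(chamber_id),
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         background = background, spots = spots),
    class = "plate_layout")
}

#' @export
print.plate_layout <- function(x, ...) {
  cat("plate_layout ", x$chamber_id, ": ", x$n_rows, " x ", x$n_cols, " (",
      nrow(x$spots), " spots), background ", x$background, "\n", sep = "")
  tab <- table(x$spots$control_role)
  cat("  roles:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Look up the spot at a grid position
#'
#' @param layout A `plate_layout`.
#' @param row,col 0-based grid coordinates.
#' @return A one-row data.frame describing the spot.
#' @export
spot_at <- function(layout, row, col) {
  stopifnot(inherits(layout, "plate_layout"))
  i <- which(layout$spots$row == row & layout$spots$col == col)
  if (length(i) != 1) stop("no spot at (", row, ", ", col, ")")
  layout$spots[i, , drop = FALSE]
}

#' Read a plate layout from CSV or JSON
#'
#' CSV layouts carry one spot per line with header columns
#' `row,col,sirna_id,target_gene,control_role,background` (0-based
#' coordinates); the chamber id is taken from an optional `chamber_id`
#' column or the file name. JSON layouts mirror the `plate_layout` structure
#' (`chamber_id`, `n_rows`, `n_cols`, `background`, `spots`).
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return A validated `plate_layout`.
#' @export
load_layout <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("layout file does not exist: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    for (f in c("n_rows", "n_cols", "spots")) {
      if (is.null(obj[[f]])) stop("JSON layout missing field: ", f)
    }
    spots <- as.data.frame(obj$spots, stringsAsFactors = FALSE)
    return(plate_layout(obj$n_rows, obj$n_cols, spots,
                        chamber_id = obj$chamber_id %||% basename(path),
                        background = obj$background %||% "control"))
  }
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop("cannot parse layout CSV: ", conditionMessage(e)))
  if (nrow(df) == 0) stop("layout file is empty: ", path)
  required <- c("row", "col", "sirna_id", "target_gene", "control_role")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("layout CSV missing columns: ", paste(missing_cols, collapse = ", "))
  }
  suppressWarnings({
    df$row <- as.integer(df$row)
    df$col <- as.integer(df$col)
  })
  if (anyNA(df$row) || anyNA(df$col)) stop("non-integer spot coordinates in ", path)
  df$target_gene[df$target_gene == ""] <- NA_character_
  background <- if ("background" %in% names(df)) unique(df$background) else "control"
  if (length(background) != 1) {
    stop("background must be constant per chamber; found: ",
         paste(background, collapse = ", "))
  }
  chamber_id <- if ("chamber_id" %in% names(df)) unique(df$chamber_id)[1] else
    tools::file_path_sans_ext(basename(path))
  plate_layout(max(df$row) + 1L, max(df$col) + 1L, df[required],
               chamber_id = chamber_id, background = background)
}

#' Write a plate layout to CSV or JSON
#'
#' @inheritParams load_layout
#' @param layout A `plate_layout`.
#' @return `path`, invisibly.
#' @export
save_layout <- function(layout, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(layout, "plate_layout"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    obj <- list(chamber_id = layout$chamber_id, n_rows = layout$n_rows,
                n_cols = layout$n_cols, background = layout$background,
                spots = layout$spots[c("row", "col", "sirna_id", "target_gene",
                                       "control_role")])
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    df <- layout$spots
    df$chamber_id <- layout$chamber_id
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  }
  invisible(path)
}

#' Validate a screen design across chambers
#'
#' Report-only check of a set of chamber layouts: per-chamber counts of
#' positive, negative and transfection-QC control spots, flags for chambers
#' lacking any control class, and the number of unique sample siRNAs covered
#' jointly by all chambers.
#'
#' @param layouts A list of `plate_layout` objects (or a single one).
#' @return A list with `chambers` (data.frame of per-chamber counts and
#'   flags) and `n_sample_sirnas` (unique sample siRNAs across the design).
#' @export
validate_design <- function(layouts) {
  if (inherits(layouts, "plate_layout")) layouts <- list(layouts)
  stopifnot(length(layouts) >= 1)
  rows <- lapply(layouts, function(l) {
    tab <- table(factor(l$spots$control_role,
                        levels = c("positive", "negative", "transfection_qc", "sample")))
    missing <- names(tab)[tab == 0 & names(tab) != "sample"]
    data.frame(chamber_id = l$chamber_id, background = l$background,
               n_spots = nrow(l$spots),
               n_positive = as.integer(tab[["positive"]]),
               n_negative = as.integer(tab[["negative"]]),
               n_transfection_qc = as.integer(tab[["transfection_qc"]]),
               n_sample = as.integer(tab[["sample"]]),
               missing_controls = paste(missing, collapse = ";"),
               flagged = length(missing) > 0,
               stringsAsFactors = FALSE)
  })
  chambers <- do.call(rbind, rows)
  sample_ids <- unique(unlist(lapply(layouts, function(l)
    l$spots$sirna_id[l$spots$control_role == "sample"])))
  list(chambers = chambers, n_sample_sirnas = length(sample_ids),
       sample_sirnas = sort(sample_ids))
}

#' Re-target a chamber layout to a different co-transfection background
#'
#' The same spotted chamber design is used under each background (control,
#' SEC23A, SEC23B); this returns a copy of `layout` with the background
#' replaced and the chamber id suffixed.
#'
#' @param layout A `plate_layout`.
#' @param background New background.
#' @return A `plate_layout`.
#' @export
with_background <- function(layout, background) {
  stopifnot(inherits(layout, "plate_layout"))
  plate_layout(layout$n_rows, layout$n_cols,
               layout$spots[c("row", "col", "sirna_id", "target_gene", "control_role")],
               chamber_id = paste0(sub("_(SEC23A|SEC23B|control)$", "", layout$chamber_id),
                                   "_", background),
               background = background)
}

#' Build the chamber layouts of a spotted double-knockdown screen
#'
#' Distributes a library of sample siRNAs over `n_chambers` chambers of
#' `n_rows` x `n_cols` spots and places control spots on every chamber:
#' strong transport inhibitors (COPB1, COPG1) as positive controls, two
#' non-targeting siRNAs (Scramble, Neg9) as negatives, an INCENP siRNA as
#' transfection QC (scored by multinucleation), and SEC23A/SEC23B-targeting
#' spots so that the single-knockdown score of each background is measurable
#' on control chambers. Unique sample siRNAs are assigned to interior spots
#' first; remaining spots are filled with duplicate sample spots.
#'
#' @param sirnas Character vector of sample siRNA identifiers (default
#'   `siCSK0001`..`siCSK0848`, two siRNAs per gene).
#' @param n_chambers Number of chambers the library is distributed over.
#' @param n_rows,n_cols Chamber grid.
#' @param n_control_each Named integer vector of control spot counts per
#'   chamber.
#' @param background Background for the returned layouts.
#' @return A list of `plate_layout` objects.
#' @export
design_screen_layouts <- function(sirnas = sprintf("siCSK%04d", 1:848),
                                  n_chambers = 4, n_rows = 16, n_cols = 24,
                                  n_control_each = c(COPB1 = 4, COPG1 = 4,
                                                     Scramble = 6, Neg9 = 6,
                                                     INCENP = 2, SEC23A = 2,
                                                     SEC23B = 2),
                                  background = "control") {
  n_spots <- n_rows * n_cols
  n_ctrl <- sum(n_control_each)
  per_chamber <- ceiling(length(sirnas) / n_chambers)
  if (per_chamber > n_spots - n_ctrl) {
    stop("library does not fit: ", per_chamber, " unique siRNAs per chamber but only ",
         n_spots - n_ctrl, " sample spots available")
  }
  roles <- c(COPB1 = "positive", COPG1 = "positive", Scramble = "negative",
             Neg9 = "negative", INCENP = "transfection_qc",
             SEC23A = "positive", SEC23B = "positive")
  chunks <- split(sirnas, ceiling(seq_along(sirnas) / per_chamber))

  grid <- expand.grid(row = 0:(n_rows - 1), col = 0:(n_cols - 1))
  # distance from plate edge; interior spots host the unique library copies
  edge_dist <- pmin(grid$row, n_rows - 1 - grid$row, grid$col, n_cols - 1 - grid$col)
  ord <- order(-edge_dist, grid$row, grid$col)
  grid <- grid[ord, ]

  # controls scattered on a coarse sublattice, at least two spots from any
  # plate edge (full, symmetric 5x5 windows: linear plate gradients cancel
  # from the window median) and far enough apart that no window sees more
  # than one spot of any control type
  n_lat_rows <- max(2, floor(sqrt(n_ctrl * n_rows / n_cols)))
  n_lat_cols <- ceiling(n_ctrl / n_lat_rows)
  ctrl_rows <- round(seq(2, n_rows - 3, length.out = n_lat_rows))
  ctrl_cols <- round(seq(2, n_cols - 3, length.out = n_lat_cols))
  lattice <- expand.grid(row = ctrl_rows, col = ctrl_cols)
  if (nrow(lattice) < n_ctrl) {
    stop("chamber too small to scatter ", n_ctrl, " control spots")
  }
  lattice <- lattice[round(seq(1, nrow(lattice), length.out = n_ctrl)), ]
  # interleave control types so duplicates of a type sit far apart
  ord <- order(stats::ave(seq_len(n_ctrl),
                          rep(names(n_control_each), n_control_each),
                          FUN = seq_along))
  ctrl_gene <- rep(names(n_control_each), n_control_each)[ord]
  ctrl_pos_idx <- match(paste(lattice$row, lattice$col),
                        paste(grid$row, grid$col))

  lapply(seq_len(n_chambers), function(k) {
    ids <- chunks[[min(k, length(chunks))]]
    sirna <- character(n_spots)
    gene <- character(n_spots)
    role <- rep("sample", n_spots)
    sirna[ctrl_pos_idx] <- paste0("si", ctrl_gene)
    gene[ctrl_pos_idx] <- ifelse(roles[ctrl_gene] %in% c("negative"), NA, ctrl_gene)
    role[ctrl_pos_idx] <- roles[ctrl_gene]
    open <- which(sirna == "")
    fill <- rep(ids, length.out = length(open))
    fill[seq_along(ids)] <- ids   # one copy of each id first, then duplicates
    sirna[open] <- fill
    gene[open] <- sub("^si", "g", fill)
    spots <- data.frame(row = grid$row, col = grid$col, sirna_id = sirna,
                        target_gene = gene, control_role = role,
                        stringsAsFactors = FALSE)
    plate_layout(n_rows, n_cols, spots,
                 chamber_id = sprintf("chamber%02d_%s", k, background),
                 background = background)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
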