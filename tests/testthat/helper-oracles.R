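# Independent brute-force statistics used as oracles: sort-based median and
# MAD, deliberately avoiding stats::median / the package's own code path.
brute_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}
brute_mad <- function(x) {
  m <- brute_median(x)
  brute_median(abs(x - m))
}
brute_transport_score <- function(xi, w) (xi - brute_median(w)) / brute_mad(w)

# Independent synergy predicate (mirrors the published rule, coded afresh)
brute_is_hit <- function(sg, sb, d, margin = 1, thr = 1.5) {
  strong <- (d <= -thr) | (d >= thr)
  strong & (abs(d - (sg + sb)) > margin)
}

# Brute-force 3D connected components (6-connectivity) by BFS; tiny stacks only
brute_cc_count <- function(mask) {
  d <- dim(mask)
  seen <- array(FALSE, d)
  count <- 0
  idx <- which(mask)
  for (start in idx) {
    if (seen[start]) next
    count <- count + 1
    queue <- start
    seen[start] <- TRUE
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      co <- arrayInd(cur, d)
      for (k in 1:3) for (s in c(-1, 1)) {
        nb <- co
        nb[k] <- nb[k] + s
        if (nb[k] < 1 || nb[k] > d[k]) next
        j <- nb[1] + d[1] * (nb[2] - 1) + d[1] * d[2] * (nb[3] - 1)
        if (mask[j] && !seen[j]) {
          seen[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
  }
  count
}

# small chamber layout for unit tests: n unique sample siRNAs + controls
tiny_layout <- function(n_rows = 8, n_cols = 10, chamber_id = "t1",
                        background = "control") {
  n <- n_rows * n_cols
  roles <- rep("sample", n)
  roles[c(12, 25)] <- "positive"
  roles[c(38, 51)] <- "negative"
  roles[64] <- "transfection_qc"
  ids <- sprintf("si%03d", seq_len(n))
  ids[roles == "positive"] <- c("siCOPB1", "siCOPG1")
  ids[roles == "negative"] <- c("siScramble", "siNeg9")
  ids[roles == "transfection_qc"] <- "siINCENP"
  grid <- expand.grid(col = 0:(n_cols - 1), row = 0:(n_rows - 1))
  spots <- data.frame(row = grid$row, col = grid$col, sirna_id = ids,
                      target_gene = sub("^si", "g", ids), control_role = roles,
                      stringsAsFactors = FALSE)
  plate_layout(n_rows, n_cols, spots, chamber_id = chamber_id,
               background = background)
}

.disk_mask_test <- function(n, cx, cy, r) {
  outer(1:n, 1:n, function(x, y) (x - cx)^2 + (y - cy)^2 <= r^2)
}
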