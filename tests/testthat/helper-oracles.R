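# Independent brute-force oracles. Everything here works on dense per-base
# arrays with explicit loops, deliberately sharing no code with the
# run-length implementation under test.

# dense per-base depth vector of length len for one chrom/strand
dense_depth <- function(cov, chrom, strand, len) {
  v <- numeric(len)
  r <- cov$runs[[chrom]][[strand]]
  if (!is.null(r) && nrow(r) > 0) {
    for (i in seq_len(nrow(r))) {
      for (b in r$start[i]:(r$end[i] - 1L)) v[b + 1L] <- r$depth[i]
    }
  }
  v
}

# literal transcription of the window rules: consecutive windows from the
# anchor, fraction-of-covered-bases (or mean) pass criterion, local
# truncation at a blocking gene's proximal edge, meta skip-through,
# distal trim to the last covered base.
oracle_scan <- function(depth, anchor, direction, blockers, params, chrom_len) {
  W <- params$window
  if ((direction == 1 && anchor >= chrom_len) || (direction == -1 && anchor <= 0))
    return(NULL)
  reach_lo <- if (direction == 1) anchor else max(0, anchor - params$max_extent)
  reach_hi <- if (direction == 1) min(chrom_len, anchor + params$max_extent) else anchor
  stop_pos <- anchor
  skipped <- character()
  k <- 0
  repeat {
    if (direction == 1) { ws <- anchor + k * W; we <- ws + W }
    else { we <- anchor - k * W; ws <- we - W }
    if (ws < reach_lo || we > reach_hi) break
    hit <- which(blockers$start < we & ws < blockers$end)
    if (length(hit) > 0 && params$mode == "local") {
      edge <- if (direction == 1) min(blockers$start[hit]) else max(blockers$end[hit])
      if (direction == 1) stop_pos <- max(stop_pos, min(edge, we))
      else stop_pos <- min(stop_pos, max(edge, ws))
      break
    }
    if (length(hit) > 0) {
      skipped <- union(skipped, blockers$gene_id[hit])
      pass <- TRUE
    } else {
      win <- depth[(ws + 1):we]
      pass <- if (params$criterion == "frac")
        sum(win >= params$min_depth) >= params$min_covered_frac * W
      else mean(win) >= params$min_depth
    }
    if (!pass) break
    stop_pos <- if (direction == 1) we else ws
    k <- k + 1
  }
  rs <- if (direction == 1) anchor else stop_pos
  re <- if (direction == 1) stop_pos else anchor
  if (re <= rs) return(NULL)
  in_skip <- rep(FALSE, re - rs)
  for (g in which(blockers$gene_id %in% skipped)) {
    for (b in max(blockers$start[g], rs):(min(blockers$end[g], re) - 1)) {
      if (b >= rs && b < re) in_skip[b - rs + 1] <- TRUE
    }
  }
  cov_base <- depth[(rs + 1):re] >= params$min_depth | in_skip
  if (!any(cov_base)) return(NULL)
  if (direction == 1) re <- rs + max(which(cov_base)) else rs <- rs + min(which(cov_base)) - 1
  if (re <= rs) return(NULL)
  list(start = rs, end = re, skipped = sort(skipped))
}

# oracle counterpart of discover_regions for one category
oracle_discover <- function(cov, blocks, genes, category, params) {
  geom <- list(DoG = c("3p", "same"), ADoG = c("3p", "opp"),
               PoG = c("5p", "same"), APoG = c("5p", "opp"))[[category]]
  out <- list()
  for (i in seq_len(nrow(blocks))) {
    bl <- blocks[i, ]
    chrom_len <- cov$chrom_lengths[[bl$chrom]]
    at3 <- geom[1] == "3p"
    if (bl$strand == "+") {
      anchor <- if (at3) bl$end else bl$start
      direction <- if (at3) 1 else -1
    } else {
      anchor <- if (at3) bl$start else bl$end
      direction <- if (at3) -1 else 1
    }
    signal <- if (geom[2] == "same") bl$strand else setdiff(c("+", "-"), bl$strand)
    blockers <- genes[genes$chrom == bl$chrom & genes$strand == signal,
                      c("gene_id", "start", "end")]
    depth <- dense_depth(cov, bl$chrom, signal, chrom_len)
    r <- oracle_scan(depth, anchor, direction, blockers, params, chrom_len)
    if (is.null(r)) next
    out[[length(out) + 1L]] <- data.frame(
      parent_block = bl$block_id, category = category, chrom = bl$chrom,
      start = r$start, end = r$end, strand = signal,
      skipped = paste(r$skipped, collapse = ","), stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(parent_block = character(), category = character(),
                      chrom = character(), start = integer(), end = integer(),
                      strand = character(), skipped = character()))
  do.call(rbind, out)
}

# per-base occupancy flattening oracle
oracle_flatten <- function(genes, chrom_len = NULL) {
  out <- list()
  for (chrom in unique(genes$chrom)) for (st in c("+", "-")) {
    g <- genes[genes$chrom == chrom & genes$strand == st, ]
    if (nrow(g) == 0) next
    L <- max(g$end) + 1L
    occ <- rep(FALSE, L + 1L)        # position i covers base i-1..i gap marker
    for (i in seq_len(nrow(g))) occ[(g$start[i] + 1L):g$end[i]] <- TRUE
    # connected components of covered bases
    rl <- rle(occ)
    pos <- cumsum(c(0, rl$lengths))
    for (j in which(rl$values)) {
      s <- pos[j]; e <- pos[j + 1L]
      members <- g$gene_id[g$start < e & s < g$end]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, strand = st, start = s, end = e,
        members = paste(sort(members), collapse = ","), stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  df[order(df$chrom, df$start, df$strand), ]
}

# random fixture helpers -----------------------------------------------------

random_genes <- function(n, chrom = "chrI", chrom_len = 20000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  start <- sample.int(chrom_len - 600, n, replace = TRUE)
  len <- sample(100:500, n, replace = TRUE)
  data.frame(gene_id = sprintf("g%03d", seq_len(n)), chrom = chrom,
             start = start, end = pmin(start + len, chrom_len),
             strand = sample(c("+", "-"), n, replace = TRUE),
             biotype = "protein_coding", stringsAsFactors = FALSE)
}

random_coverage <- function(chrom = "chrI", chrom_len = 20000, n_runs = 30,
                            max_depth = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mk <- function() {
    s <- sort(sample.int(chrom_len - 1, n_runs))
    e <- pmin(s + sample(50:900, n_runs, replace = TRUE), chrom_len)
    d <- data.frame(start = s, end = e, depth = sample.int(max_depth, n_runs, replace = TRUE))
    # drop overlapping runs so the bedGraph is well-formed
    keep <- rep(TRUE, n_runs)
    last_end <- -1
    for (i in seq_len(n_runs)) {
      if (d$start[i] < last_end) keep[i] <- FALSE else last_end <- d$end[i]
    }
    d[keep, ]
  }
  stranded_coverage(stats::setNames(list(list(`+` = mk(), `-` = mk())), chrom),
                    stats::setNames(chrom_len, chrom))
}
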