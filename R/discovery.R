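#' Parameters for the sliding-window read-through scan
#'
#' @param window Window size in bases (default 100).
#' @param min_depth Per-base depth threshold tau (default 1.0).
#' @param min_covered_frac Fraction of window bases that must reach
#'   `min_depth` for the window to pass (default 0.8; used when
#'   `criterion = "frac"`).
#' @param mode `"local"` (stop at a same-signal-strand gene) or `"meta"`
#'   (scan through it, recording the skipped gene).
#' @param max_extent Maximum scan distance from the anchor in bases.
#' @param criterion Window pass rule: `"frac"` — at least
#'   `min_covered_frac * window` bases at depth >= `min_depth` (robust to
#'   single-base spikes) — or `"mean"` — window mean depth >= `min_depth`.
#' @param step Window step in bases; defaults to `window` (non-overlapping
#'   consecutive windows).
#' @return A list of class `DiscoveryParams`.
#' @export
discovery_params <- function(window = 100L, min_depth = 1.0,
                             min_covered_frac = 0.8,
                             mode = c("local", "meta"),
                             max_extent = 50000L,
                             criterion = c("frac", "mean"),
                             step = window) {
  mode <- match.arg(mode); criterion <- match.arg(criterion)
  .assert(window >= 1, "window must be >= 1")
  .assert(min_covered_frac > 0 && min_covered_frac <= 1, "min_covered_frac in (0,1]")
  .assert(min_depth > 0, "min_depth must be > 0")
  .assert(max_extent >= window, "max_extent must be >= window")
  structure(list(window = as.integer(window), min_depth = min_depth,
                 min_covered_frac = min_covered_frac, mode = mode,
                 max_extent = as.integer(max_extent), criterion = criterion,
                 step = as.integer(step)),
            class = "DiscoveryParams")
}

.window_passes <- function(depth_win, params) {
  if (params$criterion == "frac") {
    sum(depth_win >= params$min_depth) >= params$min_covered_frac * length(depth_win)
  } else {
    mean(depth_win) >= params$min_depth
  }
}

#' Extend a read-through region from an anchor
#'
#' Walks consecutive windows of `params$window` bases away from `anchor`
#' in `direction`, extending while windows pass the coverage criterion.
#' In local mode a window touching a blocking gene stops the scan and the
#' region is truncated at that gene's proximal edge; in meta mode such
#' windows count as passing and the gene is recorded. The distal end is
#' trimmed inward to the last base at depth >= `min_depth`.
#'
#' @param cov A [stranded_coverage()] object.
#' @param chrom Chromosome.
#' @param anchor 0-based anchor coordinate (region abuts it).
#' @param direction `+1` (rightward) or `-1` (leftward).
#' @param signal_strand Strand whose coverage is scanned.
#' @param blocking_genes `data.frame` with `gene_id`, `start`, `end` of the
#'   same-signal-strand genes on `chrom` (may be empty).
#' @param params A [discovery_params()] object.
#' @return One-row `data.frame` (`chrom`, `start`, `end`, `strand`, `mode`,
#'   `mean_depth`, `skipped_gene_ids`) or `NULL` if the first window fails.
#' @export
scan_from_anchor <- function(cov, chrom, anchor, direction, signal_strand,
                             blocking_genes, params) {
  .assert(direction %in% c(1L, -1L), "direction must be +1 or -1")
  chrom_len <- cov$chrom_lengths[[chrom]]
  .assert(!is.null(chrom_len), "unknown chromosome '%s'", chrom)
  if ((direction == 1L && anchor >= chrom_len) || (direction == -1L && anchor <= 0))
    return(NULL)  # anchor at chromosome edge: nothing to scan
  W <- params$window
  if (is.null(blocking_genes) || nrow(blocking_genes) == 0)
    blocking_genes <- data.frame(gene_id = character(), start = integer(),
                                 end = integer())

  # reachable span, decoded once
  if (direction == 1L) {
    span0 <- anchor; span1 <- min(anchor + params$max_extent, chrom_len)
  } else {
    span0 <- max(anchor - params$max_extent, 0L); span1 <- anchor
  }
  depth <- .decode_depth(cov, chrom, signal_strand, span0, span1)

  stop_pos <- anchor        # current distal boundary of the raw region
  truncated <- FALSE
  skipped <- character()
  k <- 0L
  repeat {
    off <- k * params$step
    if (direction == 1L) { ws <- anchor + off; we <- ws + W } else { we <- anchor - off; ws <- we - W }
    if (ws < span0 || we > span1) break       # full window must fit
    hit <- .overlaps(blocking_genes$start, blocking_genes$end, ws, we)
    if (any(hit)) {
      if (params$mode == "local") {
        # truncate at the proximal edge of the nearest overlapping gene
        edge <- if (direction == 1L) min(blocking_genes$start[hit])
                else max(blocking_genes$end[hit])
        if (direction == 1L) stop_pos <- max(stop_pos, min(edge, we))
        else stop_pos <- min(stop_pos, max(edge, ws))
        truncated <- TRUE
        break
      }
      skipped <- union(skipped, blocking_genes$gene_id[hit])
      pass <- TRUE                            # meta: blocked window passes
    } else {
      pass <- .window_passes(depth[(ws - span0 + 1L):(we - span0)], params)
    }
    if (!pass) break
    stop_pos <- if (direction == 1L) we else ws
    k <- k + 1L
  }

  if (direction == 1L) { rs <- anchor; re <- stop_pos } else { rs <- stop_pos; re <- anchor }
  if (re <= rs) return(NULL)
  skipped_mask <- function(rs, re) {
    # bases of [rs, re) lying under a skipped gene (meta mode)
    m <- rep(FALSE, re - rs)
    if (length(skipped)) {
      sk <- blocking_genes[blocking_genes$gene_id %in% skipped, , drop = FALSE]
      for (i in seq_len(nrow(sk))) {
        a <- max(sk$start[i], rs); b <- min(sk$end[i], re)
        if (a < b) m[(a - rs + 1L):(b - rs)] <- TRUE
      }
    }
    m
  }
  # distal trim to the last base at depth >= tau (bases under skipped genes
  # count as covered so a meta region is not trimmed back through a gene)
  d <- depth[(rs - span0 + 1L):(re - span0)]
  covered <- which(d >= params$min_depth | skipped_mask(rs, re))
  if (length(covered) == 0) return(NULL)
  if (direction == 1L) re <- rs + max(covered) else rs <- rs + min(covered) - 1L
  if (re <= rs) return(NULL)
  # mean depth over region bases, excluding bases under skipped genes
  d2 <- depth[(rs - span0 + 1L):(re - span0)]
  excl <- skipped_mask(rs, re)
  md <- if (all(excl)) 0 else mean(d2[!excl])
  data.frame(chrom = chrom, start = as.integer(rs), end = as.integer(re),
             strand = signal_strand, mode = params$mode, mean_depth = md,
             skipped_gene_ids = paste(sort(skipped), collapse = ","),
             stringsAsFactors = FALSE)
}

.category_geometry <- function(block, category) {
  # returns anchor, direction, signal strand for one block and category
  plus <- block$strand == "+"
  down <- category %in% c("DoG", "ADoG")        # 3' side, else 5' side
  anchor <- if (xor(plus, down)) block$start else block$end
  direction <- if (xor(plus, down)) -1L else 1L
  signal <- if (category %in% c("DoG", "PoG")) block$strand
            else .opposite_strand(block$strand)
  list(anchor = anchor, direction = direction, signal = signal)
}

.category_prefix <- c(DoG = "do", ADoG = "ado", PoG = "po", APoG = "apo")

#' Discover read-through regions of one category for all blocks
#'
#' Per flattened gene block, anchors a scan at the block's 3' end (DoG,
#' ADoG — downstream) or 5' end (PoG, APoG — upstream), on the block
#' strand (DoG, PoG) or the opposite strand (ADoG, APoG). Blocking genes
#' are always the genes on the signal strand.
#'
#' @param cov A [stranded_coverage()] object.
#' @param blocks Output of [flatten_genes()].
#' @param genes The gene table the blocks were built from.
#' @param category One of `"DoG"`, `"ADoG"`, `"PoG"`, `"APoG"`.
#' @param params A [discovery_params()] object.
#' @return Region `data.frame`; at most one region per block, named
#'   `do`/`ado`/`po`/`apo` + parent block name.
#' @export
discover_regions <- function(cov, blocks, genes, category, params) {
  .assert(category %in% names(.category_prefix), "unknown category '%s'", category)
  out <- list()
  for (i in seq_len(nrow(blocks))) {
    block <- blocks[i, ]
    if (!block$chrom %in% names(cov$chrom_lengths)) next
    geo <- .category_geometry(block, category)
    blockers <- genes[genes$chrom == block$chrom & genes$strand == geo$signal,
                      c("gene_id", "start", "end"), drop = FALSE]
    reg <- scan_from_anchor(cov, block$chrom, geo$anchor, geo$direction,
                            geo$signal, blockers, params)
    if (is.null(reg)) next
    reg$region_id <- paste0(.category_prefix[[category]], block$block_id)
    reg$category <- category
    reg$parent_block <- block$block_id
    out[[length(out) + 1L]] <- reg
  }
  if (length(out) == 0) return(.empty_region_df())
  out <- do.call(rbind, out)
  cols <- names(.empty_region_df())
  rownames(out) <- NULL
  out[, cols]
}

#' Discover all four region categories
#'
#' @inheritParams discover_regions
#' @param categories Character vector of categories to call.
#' @return Single region `data.frame` with a `category` column.
#' @export
discover_all_categories <- function(cov, blocks, genes, params,
                                    categories = c("DoG", "ADoG", "PoG", "APoG")) {
  do.call(rbind, lapply(categories, function(cat)
    discover_regions(cov, blocks, genes, cat, params)))
}

#' Apply the published post-discovery filters
#'
#' Three rules, in order: (1) DoGs with any same-strand overlap to an
#' operon are removed (polycistronic transcription, not read-through);
#' (2) PoGs with any overlap to a surviving same-strand DoG are removed;
#' (3) ADoGs and APoGs with any overlap, on their signal strand, to a gene
#' or surviving DoG on that strand are removed. Every removal is logged
#' with the rule that fired.
#'
#' @param regions Region `data.frame` (all categories together).
#' @param genes Gene table.
#' @param operons Operon table from [parse_operons()] (or `NULL`).
#' @return List with `regions` (survivors) and `removed`
#'   (`region_id`, `rule`, `detail`).
#' @export
filter_regions <- function(regions, genes, operons = NULL) {
  removed <- data.frame(region_id = character(), rule = character(),
                        detail = character(), stringsAsFactors = FALSE)
  drop_one <- function(id, rule, detail) {
    removed <<- rbind(removed, data.frame(region_id = id, rule = rule,
                                          detail = detail, stringsAsFactors = FALSE))
  }
  is_dog <- regions$category == "DoG"
  # rule 1: DoG vs same-strand operon
  if (!is.null(operons) && nrow(operons) > 0) {
    for (i in which(is_dog)) {
      hit <- operons$chrom == regions$chrom[i] &
             operons$strand == regions$strand[i] &
             .overlaps(operons$start, operons$end, regions$start[i], regions$end[i])
      if (any(hit))
        drop_one(regions$region_id[i], "operon_same_strand",
                 paste(operons$operon_id[hit], collapse = ","))
    }
  }
  surviving_dogs <- regions[is_dog & !(regions$region_id %in% removed$region_id), ,
                            drop = FALSE]
  # rule 2: PoG vs surviving same-strand DoG
  for (i in which(regions$category == "PoG")) {
    hit <- surviving_dogs$chrom == regions$chrom[i] &
           surviving_dogs$strand == regions$strand[i] &
           .overlaps(surviving_dogs$start, surviving_dogs$end,
                     regions$start[i], regions$end[i])
    if (any(hit))
      drop_one(regions$region_id[i], "pog_vs_dog",
               paste(surviving_dogs$region_id[hit], collapse = ","))
  }
  # rule 3: ADoG/APoG vs gene or surviving DoG on the signal strand
  for (i in which(regions$category %in% c("ADoG", "APoG"))) {
    s <- regions$strand[i]  # signal strand
    ghit <- genes$chrom == regions$chrom[i] & genes$strand == s &
            .overlaps(genes$start, genes$end, regions$start[i], regions$end[i])
    dhit <- surviving_dogs$chrom == regions$chrom[i] & surviving_dogs$strand == s &
            .overlaps(surviving_dogs$start, surviving_dogs$end,
                      regions$start[i], regions$end[i])
    if (any(ghit) || any(dhit))
      drop_one(regions$region_id[i], "antisense_vs_opposite",
               paste(c(genes$gene_id[ghit], surviving_dogs$region_id[dhit]),
                     collapse = ","))
  }
  list(regions = regions[!(regions$region_id %in% removed$region_id), , drop = FALSE],
       removed = removed)
}

#' Genes overlapped by read-through transcription
#'
#' A gene is "overlapped" if (a) an ADoG exists whose parent block contains
#' the gene, or (b) a DoG on the opposite strand overlaps the gene's
#' interval by at least one base. Such genes receive antisense reads from
#' read-through rather than from their own antisense transcription.
#'
#' @param genes Gene table.
#' @param dogs,adogs Filtered DoG and ADoG region tables.
#' @return `data.frame` with `gene_id`, `witnesses` (comma-separated region
#'   ids), `via_adog`, `via_opposite_dog` for each overlapped gene.
#' @export
associate_overlapped_genes <- function(genes, dogs, adogs) {
  out <- list()
  adog_members <- strsplit(adogs$parent_block, ",", fixed = TRUE)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    via_a <- if (nrow(adogs)) vapply(adog_members, function(m) g$gene_id %in% m, TRUE)
             else logical(0)
    via_d <- if (nrow(dogs)) dogs$chrom == g$chrom &
                             dogs$strand == .opposite_strand(g$strand) &
                             .overlaps(dogs$start, dogs$end, g$start, g$end)
             else logical(0)
    wit <- c(adogs$region_id[via_a], dogs$region_id[via_d])
    if (length(wit) == 0) next
    out[[length(out) + 1L]] <- data.frame(
      gene_id = g$gene_id, witnesses = paste(wit, collapse = ","),
      via_adog = any(via_a), via_opposite_dog = any(via_d),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(gene_id = character(), witnesses = character(),
                      via_adog = logical(), via_opposite_dog = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
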