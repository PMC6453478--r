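#' Antisense/sense ratio analysis between two conditions
#'
#' For each gene, compares the antisense-to-sense balance of input RNA
#' between a condition and a reference. Genes are scored only when the
#' pooled mean count over {sense, antisense} x {condition, reference}
#' reaches `min_mean` (default 20), and the ratio fold change is
#' `log2[(anti + c)/(sense + c)]` in the condition minus the same in the
#' reference, with pseudocount `c`.
#'
#' @param sense_cond,sense_ref,anti_cond,anti_ref Named numeric vectors of
#'   mean (normalized) counts per gene for each group; identical gene
#'   universe required.
#' @param min_mean Pooled-mean floor for scoring a gene.
#' @param pseudocount Added to numerator and denominator of each ratio.
#' @return List with `records` (per scored gene: counts, `pooled_mean`,
#'   `log2_ratio_fc`, `log2fc_sense`, `log2fc_antisense`) and `summary`
#'   (`n_scored`, `n_ratio_up`, `n_ratio_down`, `n_ratio_zero`,
#'   `n_sense_up`, `n_antisense_up`). "Up" means strictly positive log2FC.
#' @export
antisense_sense_analysis <- function(sense_cond, anti_cond, sense_ref, anti_ref,
                                     min_mean = 20, pseudocount = 1) {
  ids <- names(sense_cond)
  .assert(!is.null(ids), "count vectors must be named by gene")
  .assert(identical(ids, names(anti_cond)) && identical(ids, names(sense_ref)) &&
          identical(ids, names(anti_ref)),
          "all four count vectors must share the same gene universe/order")
  pooled <- (sense_cond + anti_cond + sense_ref + anti_ref) / 4
  keep <- pooled >= min_mean
  lr <- function(a, s) log2((a + pseudocount) / (s + pseudocount))
  rec <- data.frame(
    gene_id = ids[keep],
    sense_cond = sense_cond[keep], anti_cond = anti_cond[keep],
    sense_ref = sense_ref[keep], anti_ref = anti_ref[keep],
    pooled_mean = pooled[keep],
    log2_ratio_fc = lr(anti_cond[keep], sense_cond[keep]) -
                    lr(anti_ref[keep], sense_ref[keep]),
    log2fc_sense = log2((sense_cond[keep] + pseudocount) /
                        (sense_ref[keep] + pseudocount)),
    log2fc_antisense = log2((anti_cond[keep] + pseudocount) /
                            (anti_ref[keep] + pseudocount)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(records = rec,
       summary = list(
         n_scored = nrow(rec),
         n_ratio_up = sum(rec$log2_ratio_fc > 0),
         n_ratio_down = sum(rec$log2_ratio_fc < 0),
         n_ratio_zero = sum(rec$log2_ratio_fc == 0),
         n_sense_up = sum(rec$log2fc_sense > 0),
         n_antisense_up = sum(rec$log2fc_antisense > 0)))
}

#' Upper-tail hypergeometric overlap test
#'
#' Tests whether two gene sets drawn from a common universe overlap more
#' than expected by chance: `P(X >= k)` where `X` is hypergeometric with
#' the universe size, set-A size and set-B size.
#'
#' @param universe Character vector of all eligible ids.
#' @param set_a,set_b Subsets of the universe.
#' @return List with `N`, `K`, `n`, `k` and `pvalue`.
#' @export
hypergeom_overlap <- function(universe, set_a, set_b) {
  universe <- unique(universe); set_a <- unique(set_a); set_b <- unique(set_b)
  .assert(all(set_a %in% universe) && all(set_b %in% universe),
          "sets must be subsets of the universe")
  N <- length(universe); K <- length(set_a); n <- length(set_b)
  k <- length(intersect(set_a, set_b))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(N = N, K = K, n = n, k = k, pvalue = p)
}

#' Repeat-overlap enrichment of regions against a shuffled background
#'
#' Counts how many regions overlap at least one repeat element and
#' compares against a permutation null in which length-matched intervals
#' are placed uniformly at random within allowed intergenic background
#' intervals on the same chromosome.
#'
#' @param regions,repeat_intervals `data.frame`s with `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param background Allowed placement intervals (gene bodies excluded).
#' @param n_shuffles Number of permutations.
#' @param seed Integer seed; the permutation stream is local to the call.
#' @return List with `observed`, `empirical_p`
#'   (`(1 + #\{null >= observed\}) / (1 + n_shuffles)`) and `null` (the
#'   permuted statistics).
#' @export
repeat_enrichment <- function(regions, repeat_intervals, background,
                              n_shuffles = 1000, seed = 1) {
  count_hits <- function(regs) {
    hits <- 0L
    for (i in seq_len(nrow(regs))) {
      ov <- repeat_intervals$chrom == regs$chrom[i] &
            .overlaps(repeat_intervals$start, repeat_intervals$end,
                      regs$start[i], regs$end[i])
      if (any(ov)) hits <- hits + 1L
    }
    hits
  }
  lens <- regions$end - regions$start
  # feasibility + placement weights per region
  placements <- lapply(seq_len(nrow(regions)), function(i) {
    bg <- background[background$chrom == regions$chrom[i], , drop = FALSE]
    room <- bg$end - bg$start - lens[i]
    ok <- room >= 0
    .assert(any(ok), "region %s (length %d) longer than every background interval on %s",
            rownames(regions)[i] %||% i, lens[i], regions$chrom[i])
    list(bg = bg[ok, , drop = FALSE], w = room[ok] + 1)
  })
  observed <- count_hits(regions)
  null <- withr::with_seed(seed, {
    vapply(seq_len(n_shuffles), function(rep) {
      sh <- regions
      for (i in seq_len(nrow(sh))) {
        pl <- placements[[i]]
        j <- if (nrow(pl$bg) == 1) 1L else sample.int(nrow(pl$bg), 1, prob = pl$w)
        off <- sample.int(pl$w[j], 1) - 1L
        sh$start[i] <- pl$bg$start[j] + off
        sh$end[i] <- sh$start[i] + lens[i]
      }
      count_hits(sh)
    }, 0L)
  })
  list(observed = observed,
       empirical_p = (1 + sum(null >= observed)) / (1 + n_shuffles),
       null = null)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
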