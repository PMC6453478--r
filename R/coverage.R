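#' Stranded base-resolution coverage
#'
#' `StrandedCoverage` stores per-chromosome, per-strand depth as sorted,
#' non-overlapping run-length segments `(start, end, depth)` in 0-based
#' half-open coordinates. Absent runs mean depth 0. The constructor
#' canonicalizes: runs are sorted, zero-depth runs dropped, and adjacent
#' equal-depth runs merged, so equal coverages compare equal.
#'
#' @param runs Named list: `runs[[chrom]][[strand]]` is a `data.frame` with
#'   columns `start`, `end`, `depth`.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @return An object of class `StrandedCoverage`.
#' @export
stranded_coverage <- function(runs, chrom_lengths) {
  .assert(!is.null(names(chrom_lengths)), "chrom_lengths must be named")
  out <- list(runs = list(), chrom_lengths = chrom_lengths)
  for (chrom in names(runs)) {
    .assert(chrom %in% names(chrom_lengths), "unknown chromosome '%s'", chrom)
    out$runs[[chrom]] <- list()
    for (strand in names(runs[[chrom]])) {
      .assert(strand %in% .strands, "strand must be '+' or '-'")
      out$runs[[chrom]][[strand]] <-
        .canonicalize_runs(runs[[chrom]][[strand]], chrom_lengths[[chrom]], chrom)
    }
  }
  structure(out, class = "StrandedCoverage")
}

.empty_runs <- function() {
  data.frame(start = integer(), end = integer(), depth = numeric())
}

.canonicalize_runs <- function(df, chrom_len, chrom) {
  if (is.null(df) || nrow(df) == 0) return(.empty_runs())
  df <- data.frame(start = as.integer(df$start), end = as.integer(df$end),
                   depth = as.numeric(df$depth))
  .assert(all(df$depth >= 0), "negative depth on %s", chrom)
  .assert(all(df$start < df$end), "empty run on %s", chrom)
  .assert(all(df$start >= 0) && all(df$end <= chrom_len),
          "coverage run beyond bounds of %s (length %d)", chrom, chrom_len)
  df <- df[order(df$start), , drop = FALSE]
  .assert(all(df$start[-1] >= df$end[-nrow(df)]),
          "overlapping coverage runs on %s: ill-formed bedGraph", chrom)
  df <- df[df$depth > 0, , drop = FALSE]
  if (nrow(df) <= 1) { rownames(df) <- NULL; return(df) }
  # merge adjacent equal-depth runs
  joinable <- c(FALSE, df$start[-1] == df$end[-nrow(df)] &
                        df$depth[-1] == df$depth[-nrow(df)])
  grp <- cumsum(!joinable)
  out <- data.frame(start = tapply(df$start, grp, min),
                    end = tapply(df$end, grp, max),
                    depth = df$depth[!joinable])
  rownames(out) <- NULL
  out$start <- as.integer(out$start); out$end <- as.integer(out$end)
  out
}

#' @export
print.StrandedCoverage <- function(x, ...) {
  cat("StrandedCoverage:", length(x$chrom_lengths), "chromosome(s)\n")
  for (chrom in names(x$chrom_lengths)) {
    n <- vapply(.strands, function(s) nrow(.runs_of(x, chrom, s)), 0L)
    cat(sprintf("  %s (%d bp): %d runs (+), %d runs (-)\n",
                chrom, x$chrom_lengths[[chrom]], n[1], n[2]))
  }
  invisible(x)
}

.runs_of <- function(cov, chrom, strand) {
  r <- cov$runs[[chrom]][[strand]]
  if (is.null(r)) .empty_runs() else r
}

#' Load a plus/minus bedGraph pair into stranded coverage
#'
#' @param plus_path,minus_path bedGraph files (0-based half-open, 4 columns)
#'   for the two strands.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @return A [stranded_coverage()] object.
#' @export
load_bedgraph_pair <- function(plus_path, minus_path, chrom_lengths) {
  runs <- list()
  for (p in list(c("+", plus_path), c("-", minus_path))) {
    gr <- rtracklayer::import(p[2], format = "bedGraph")
    .assert(all(gr$score >= 0), "negative depth in %s", p[2])
    for (chrom in unique(as.character(GenomicRanges::seqnames(gr)))) {
      g <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
      df <- data.frame(start = BiocGenerics::start(g) - 1L,
                       end = BiocGenerics::end(g), depth = g$score)
      runs[[chrom]][[p[1]]] <- df
    }
  }
  stranded_coverage(runs, chrom_lengths)
}

#' Write one strand of coverage as bedGraph
#'
#' @param cov A [stranded_coverage()] object.
#' @param strand `"+"` or `"-"`.
#' @param path Output path.
#' @export
write_bedgraph <- function(cov, strand, path) {
  rows <- lapply(names(cov$chrom_lengths), function(chrom) {
    r <- .runs_of(cov, chrom, strand)
    if (nrow(r) == 0) return(NULL)
    data.frame(chrom = chrom, r)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) rows <- data.frame(chrom = character(), start = integer(),
                                        end = integer(), depth = numeric())
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Sum of per-base depth over an interval
#'
#' @param cov A [stranded_coverage()] object.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param start,end 0-based half-open query interval.
#' @return Numeric; `sum(depth(b))` for bases `b` in `[start, end)`.
#' @export
interval_sum <- function(cov, chrom, strand, start, end) {
  .assert(chrom %in% names(cov$chrom_lengths), "unknown chromosome '%s'", chrom)
  .assert(start >= 0 && start < end && end <= cov$chrom_lengths[[chrom]],
          "query [%s,%s) out of bounds on %s", start, end, chrom)
  r <- .runs_of(cov, chrom, strand)
  if (nrow(r) == 0) return(0)
  sum(.overlap_width(start, end, r$start, r$end) * r$depth)
}

# dense per-base depth over [start, end) — used by the window scan
.decode_depth <- function(cov, chrom, strand, start, end) {
  r <- .runs_of(cov, chrom, strand)
  out <- numeric(end - start)
  if (nrow(r) == 0) return(out)
  keep <- .overlaps(r$start, r$end, start, end)
  for (i in which(keep)) {
    a <- max(r$start[i], start) - start + 1L
    b <- min(r$end[i], end) - start
    out[a:b] <- r$depth[i]
  }
  out
}

#' Integer feature counts from coverage
#'
#' Estimates read counts per feature as the depth sum over the feature on
#' the relevant strand divided by the read length, rounded half-up. With
#' `antisense = TRUE` the opposite strand of each feature is counted,
#' quantifying antisense transcription over the feature.
#'
#' @param cov A [stranded_coverage()] object.
#' @param features `data.frame` with `chrom`, `start`, `end`, `strand` and
#'   an id column (first of `gene_id`/`region_id`/`feature_id`/`name`).
#' @param read_length Library read length in bases.
#' @param antisense Count the strand opposite each feature?
#' @return Named integer vector of counts.
#' @export
count_features <- function(cov, features, read_length, antisense = FALSE) {
  .assert(read_length >= 1, "read_length must be >= 1")
  id_col <- intersect(c("gene_id", "region_id", "feature_id", "name"),
                      names(features))[1]
  .assert(!is.na(id_col), "features need an id column")
  n <- nrow(features)
  counts <- integer(n)
  for (i in seq_len(n)) {
    s <- if (antisense) .opposite_strand(features$strand[i]) else features$strand[i]
    tot <- interval_sum(cov, features$chrom[i], s, features$start[i], features$end[i])
    counts[i] <- as.integer(floor(tot / read_length + 0.5))  # round half-up
  }
  names(counts) <- features[[id_col]]
  counts
}

#' Read a chromosome sizes file (2-column TSV)
#'
#' @param path TSV with columns chrom, length.
#' @return Named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  stats::setNames(as.integer(df[[2]]), df[[1]])
}
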