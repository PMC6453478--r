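#' Read gene models from a GTF file
#'
#' Parses one feature type from a GTF annotation into a gene table using
#' 0-based half-open coordinates internally (GTF is 1-based closed; the
#' conversion happens here and nowhere else).
#'
#' @param path Path to a GTF file.
#' @param feature_type GTF column-3 feature to keep (default `"gene"`).
#' @param id_attribute Attribute naming each feature (default `"gene_id"`).
#' @param biotype_attribute Attribute carrying the biotype; the first of
#'   these present in the file is used. Features without it get `NA`.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` and `biotype`; `start`/`end` are 0-based half-open.
#' @details Records with strand `"."` are rejected: the discovery scan is
#'   strand-aware and unstranded gene models cannot anchor a region.
#'   Duplicate ids are an error, as are malformed lines (reported with
#'   their line number).
#' @export
parse_gtf <- function(path, feature_type = "gene", id_attribute = "gene_id",
                      biotype_attribute = c("biotype", "gene_biotype")) {
  .assert(file.exists(path), "GTF file not found: %s", path)
  .validate_gtf_lines(path)
  if (length(readLines(path, n = 1L, warn = FALSE)) == 0)
    return(.empty_gene_df())
  gr <- rtracklayer::import(path, format = "gtf")
  if (length(gr) == 0) return(.empty_gene_df())
  gr <- gr[as.character(gr$type) == feature_type]
  if (length(gr) == 0) return(.empty_gene_df())
  mc <- S4Vectors::mcols(gr)
  .assert(id_attribute %in% names(mc),
          "GTF attribute '%s' absent from '%s' features", id_attribute, feature_type)
  ids <- as.character(mc[[id_attribute]])
  .assert(!anyNA(ids), "feature without '%s' attribute", id_attribute)
  dup <- unique(ids[duplicated(ids)])
  .assert(length(dup) == 0, "duplicate %s in GTF: %s", id_attribute,
          paste(utils::head(dup, 5), collapse = ", "))
  strand <- as.character(BiocGenerics::strand(gr))
  .assert(all(strand %in% .strands),
          "unstranded ('.') %s records are not allowed", feature_type)
  bt_col <- intersect(biotype_attribute, names(mc))
  biotype <- if (length(bt_col)) as.character(mc[[bt_col[1]]]) else rep(NA_character_, length(gr))
  out <- data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = strand,
    biotype = biotype,
    stringsAsFactors = FALSE
  )
  .assert(all(out$start < out$end), "gene with non-positive length in GTF")
  out[order(out$chrom, out$start, out$end, out$gene_id), , drop = FALSE]
}

.empty_gene_df <- function() {
  data.frame(gene_id = character(), chrom = character(), start = integer(),
             end = integer(), strand = character(), biotype = character(),
             stringsAsFactors = FALSE)
}

# cheap structural validation so malformed lines are reported by number
.validate_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(lines)
  nf <- lengths(strsplit(lines[keep], "\t", fixed = TRUE))
  bad <- which(keep)[nf < 9]
  .assert(length(bad) == 0, "malformed GTF line %d in %s (fewer than 9 tab-separated fields)",
          if (length(bad)) bad[1] else 0L, path)
  invisible(TRUE)
}

#' Read operon records
#'
#' Operons may be supplied either as GTF features of a configurable feature
#' type or as a BED file (decided by extension, or forced with `format`).
#'
#' @param path GTF or BED path.
#' @param format `"auto"`, `"gtf"` or `"bed"`.
#' @param feature_type GTF feature type holding operons.
#' @param id_attribute GTF attribute naming each operon.
#' @return `data.frame` with `operon_id`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @export
parse_operons <- function(path, format = c("auto", "gtf", "bed"),
                          feature_type = "operon", id_attribute = "gene_id") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gtf"
  if (format == "gtf") {
    g <- parse_gtf(path, feature_type = feature_type, id_attribute = id_attribute)
    return(data.frame(operon_id = g$gene_id, chrom = g$chrom, start = g$start,
                      end = g$end, strand = g$strand, stringsAsFactors = FALSE))
  }
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name", "score", "strand")[1:6])
  .assert(ncol(bed) >= 6, "operon BED must have 6 columns (strand required)")
  data.frame(operon_id = as.character(bed$name), chrom = bed$chrom,
             start = as.integer(bed$start), end = as.integer(bed$end),
             strand = .norm_strand(bed$strand), stringsAsFactors = FALSE)
}

#' Flatten overlapping same-strand genes into blocks
#'
#' Read-through discovery anchors at the outermost edge of a run of
#' overlapping same-strand gene models, so overlapping-or-touching genes on
#' one strand are merged into maximal "flat blocks" first. A region
#' downstream of a nested gene then starts at the end of the enclosing
#' block, not at the inner gene's end.
#'
#' @param genes Gene table as returned by [parse_gtf()].
#' @return `data.frame` with `block_id`, `chrom`, `start`, `end`, `strand`
#'   and `member_gene_ids` (comma-separated, sorted). `block_id` is the
#'   sorted member ids joined with `","` — deterministic for a given input.
#' @export
flatten_genes <- function(genes) {
  if (nrow(genes) == 0) {
    return(data.frame(block_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      member_gene_ids = character(), stringsAsFactors = FALSE))
  }
  .assert(all(genes$strand %in% .strands), "gene strand must be '+' or '-'")
  out <- list()
  for (key in unique(paste(genes$chrom, genes$strand))) {
    g <- genes[paste(genes$chrom, genes$strand) == key, , drop = FALSE]
    g <- g[order(g$start, g$end), , drop = FALSE]
    # touching genes (end == next start) merge: cummax sweep
    cm <- cummax(g$end)
    new_block <- c(TRUE, g$start[-1] > cm[-nrow(g)])
    grp <- cumsum(new_block)
    for (b in split(seq_len(nrow(g)), grp)) {
      ids <- sort(g$gene_id[b])
      out[[length(out) + 1L]] <- data.frame(
        block_id = paste(ids, collapse = ","),
        chrom = g$chrom[b[1]], start = min(g$start[b]), end = max(g$end[b]),
        strand = g$strand[b[1]],
        member_gene_ids = paste(ids, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write called read-through regions to BED, GTF or a TSV table
#'
#' @param regions Region table from [discover_regions()] / [filter_regions()].
#' @param path Output file.
#' @param format `"bed"` (BED6; score = mean coverage x 100, rounded),
#'   `"gtf"` (1-based closed, feature = category) or `"table"` (TSV of all
#'   columns).
#' @export
write_regions <- function(regions, path, format = c("bed", "gtf", "table")) {
  format <- match.arg(format)
  if (format == "bed") {
    bed <- data.frame(regions$chrom, regions$start, regions$end,
                      regions$region_id, round(regions$mean_depth * 100),
                      regions$strand)
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else if (format == "gtf") {
    attrs <- sprintf('region_id "%s"; parent_block "%s"; mode "%s";',
                     regions$region_id, regions$parent_block, regions$mode)
    gtf <- data.frame(regions$chrom, "dogcatchr", regions$category,
                      regions$start + 1L, regions$end,
                      round(regions$mean_depth * 100), regions$strand, ".", attrs)
    utils::write.table(gtf, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    utils::write.table(regions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a BED6 file of regions (round-trip helper)
#'
#' @param path BED6 file written by [write_regions()].
#' @return `data.frame` with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (0-based half-open).
#' @export
read_regions_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  .assert(ncol(bed) == 6, "expected BED6, got %d columns", ncol(bed))
  names(bed) <- c("chrom", "start", "end", "name", "score", "strand")
  bed$strand <- .norm_strand(bed$strand)
  bed
}
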