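#' @keywords internal
"_PACKAGE"

## Internal coordinate convention: 0-based half-open [start, end) everywhere.
## Conversion to/from 1-based closed happens only at GTF file boundaries.

# vectorized half-open interval overlap: does [s1,e1) intersect [s2,e2)?
.overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

# amount of overlap between one interval and a vector of intervals
.overlap_width <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

.assert <- function(cond, ...) if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)

.strands <- c("+", "-")

.opposite_strand <- function(strand) ifelse(strand == "+", "-", "+")

# Deterministic substream seeds: one base seed per scenario, split by a
# named substream so genome/coverage/counts are independently reproducible.
.substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

.empty_region_df <- function() {
  data.frame(
    region_id = character(), category = character(), parent_block = character(),
    chrom = character(), start = integer(), end = integer(),
    strand = character(), mode = character(), mean_depth = numeric(),
    skipped_gene_ids = character(), stringsAsFactors = FALSE
  )
}

# normalize a strand column coming from external files ("-" variants)
.norm_strand <- function(x) {
  x <- as.character(x)
  x[x %in% c("−")] <- "-"
  x
}
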