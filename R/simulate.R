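#' Define a synthetic read-through scenario
#'
#' A scenario bundles every parameter of the synthetic test bed:
#' annotation geometry, planted read-through regions, the NB generative
#' model for count matrices, and the sample design. All randomness flows
#' from `seed`, split into named substreams so the genome, coverage and
#' counts are independently reproducible.
#'
#' @param seed Integer master seed.
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome in bases.
#' @param n_genes Genes per chromosome.
#' @param gene_length_range,intergenic_range Min/max gene length and
#'   intergenic gap (bases).
#' @param operon_prob Probability that a run of adjacent same-strand genes
#'   is recorded as an operon.
#' @param baseline_depth Read depth over gene bodies.
#' @param planted `data.frame` with `gene_index` (global index into the
#'   generated gene table), `category` (DoG/ADoG/PoG/APoG), `length`,
#'   `depth`, `condition_specific` (logical: present only in non-reference
#'   samples).
#' @param taper Length of the linear depth taper at each planted region's
#'   distal end (default 100 = one scan window, so boundary recovery is
#'   non-trivial).
#' @param ip_boost Multiplier applied to planted-region depth in IP
#'   samples of the non-reference condition, emulating immunoprecipitation
#'   enrichment of read-through transcripts (default 1 = no enrichment).
#' @param noise `"none"` or `"poisson"` (depth resampled per 50-bp chunk).
#' @param nb List: `dispersion`, `baseline_mean`, `log2fc` (interaction
#'   effect for planted count features), `prop_planted`.
#' @param samples List: `conditions` (reference first), `n_per_cell`
#'   (replicates per condition x fraction cell).
#' @param read_length Library read length.
#' @return A list of class `dog_scenario`.
#' @export
dog_scenario <- function(seed = 1L, n_chroms = 1L, chrom_length = 100000L,
                         n_genes = 10L, gene_length_range = c(1000L, 3000L),
                         intergenic_range = c(2000L, 6000L), operon_prob = 0,
                         baseline_depth = 10, planted = NULL, taper = 100L,
                         ip_boost = 1, noise = c("none", "poisson"),
                         nb = list(dispersion = 0.05, baseline_mean = 500,
                                   log2fc = 3.0, prop_planted = 0.1),
                         samples = list(conditions = c("WT", "HS"), n_per_cell = 3L),
                         read_length = 50L) {
  noise <- match.arg(noise)
  .assert(seed == as.integer(seed) && seed >= 0, "seed must be a non-negative integer")
  structure(list(seed = as.integer(seed), n_chroms = n_chroms,
                 chrom_length = as.integer(chrom_length), n_genes = n_genes,
                 gene_length_range = gene_length_range,
                 intergenic_range = intergenic_range, operon_prob = operon_prob,
                 baseline_depth = baseline_depth, planted = planted,
                 taper = as.integer(taper), ip_boost = ip_boost,
                 noise = noise, nb = nb,
                 samples = samples, read_length = as.integer(read_length)),
            class = "dog_scenario")
}

#' Generate the synthetic annotation
#'
#' Genes with random lengths and gaps; strand chosen at random per gene so
#' both strand geometries and adjacent same-strand pairs occur. Runs of
#' adjacent same-strand genes become operon records with probability
#' `operon_prob`. Biotypes are mostly protein_coding with occasional
#' ncRNA.
#'
#' @param scenario A [dog_scenario()].
#' @return List with `genes`, `operons`, `chrom_lengths`.
#' @export
make_genome <- function(scenario) {
  withr::with_seed(.substream_seed(scenario$seed, "genome"), {
    genes <- list(); operons <- list()
    chroms <- paste0("chr", utils::as.roman(seq_len(scenario$n_chroms)))
    for (chrom in chroms) {
      pos <- sample(scenario$intergenic_range[1]:scenario$intergenic_range[2], 1)
      for (i in seq_len(scenario$n_genes)) {
        len <- sample(scenario$gene_length_range[1]:scenario$gene_length_range[2], 1)
        gap <- sample(scenario$intergenic_range[1]:scenario$intergenic_range[2], 1)
        .assert(pos + len + gap <= scenario$chrom_length,
                "infeasible packing: %d genes do not fit in %d bp",
                scenario$n_genes, scenario$chrom_length)
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = sprintf("%s_g%02d", chrom, i), chrom = chrom,
          start = pos, end = pos + len,
          strand = sample(.strands, 1),
          biotype = sample(c("protein_coding", "ncRNA"), 1, prob = c(0.85, 0.15)),
          stringsAsFactors = FALSE)
        pos <- pos + len + gap
      }
    }
    genes <- do.call(rbind, genes)
    for (chrom in unique(genes$chrom)) {
      g <- genes[genes$chrom == chrom, ]
      run <- cumsum(c(TRUE, g$strand[-1] != g$strand[-nrow(g)]))
      for (r in split(seq_len(nrow(g)), run)) {
        if (length(r) >= 2 && stats::runif(1) < scenario$operon_prob) {
          operons[[length(operons) + 1L]] <- data.frame(
            operon_id = sprintf("op_%s_%d", chrom, r[1]), chrom = chrom,
            start = min(g$start[r]), end = max(g$end[r]), strand = g$strand[r[1]],
            stringsAsFactors = FALSE)
        }
      }
    }
    operons <- if (length(operons)) do.call(rbind, operons)
               else data.frame(operon_id = character(), chrom = character(),
                               start = integer(), end = integer(),
                               strand = character(), stringsAsFactors = FALSE)
    list(genes = genes, operons = operons,
         chrom_lengths = stats::setNames(rep(scenario$chrom_length,
                                             scenario$n_chroms), chroms))
  })
}

# planted-region geometry for one gene and category (genes here never
# overlap, so the gene is its own flat block)
.planted_interval <- function(gene, category, len) {
  geo <- .category_geometry(gene, category)
  if (geo$direction == 1L) c(geo$anchor, geo$anchor + len)
  else c(geo$anchor - len, geo$anchor)
}

#' Generate per-sample stranded coverage with planted read-through
#'
#' Gene bodies receive `baseline_depth` on their own strand in every
#' sample. Each planted region receives its specified depth on its signal
#' strand, decaying linearly to zero over the final `taper` bases at the
#' distal end; condition-specific regions are absent from reference
#' samples. The exact planted intervals are returned as a truth table.
#'
#' @param scenario A [dog_scenario()].
#' @param genome Output of [make_genome()].
#' @return List with `coverage` (named list of [stranded_coverage()], one
#'   per sample), `truth` (planted intervals), `design` (sample sheet).
#' @export
make_coverage <- function(scenario, genome) {
  design <- .scenario_design(scenario)
  planted <- scenario$planted
  truth <- NULL
  if (!is.null(planted) && nrow(planted) > 0) {
    truth <- do.call(rbind, lapply(seq_len(nrow(planted)), function(i) {
      gene <- genome$genes[planted$gene_index[i], ]
      geo <- .category_geometry(gene, planted$category[i])
      iv <- .planted_interval(gene, planted$category[i], planted$length[i])
      .assert(iv[1] >= 0 && iv[2] <= scenario$chrom_length,
              "planted region for %s exceeds chromosome bounds", gene$gene_id)
      clash <- genome$genes$chrom == gene$chrom &
               genome$genes$strand == geo$signal &
               .overlaps(genome$genes$start, genome$genes$end, iv[1], iv[2])
      .assert(!any(clash),
              "planted %s at %s collides with same-strand gene(s): %s",
              planted$category[i], gene$gene_id,
              paste(genome$genes$gene_id[clash], collapse = ","))
      # detectable boundary at unit depth: the linear taper drops below
      # depth 1 over its final (tp+1)/depth bases, which no threshold scan
      # at tau >= 1 can see; boundary-recovery is scored against this edge
      tp <- min(scenario$taper, iv[2] - iv[1])
      sub <- min(ceiling((tp + 1) / planted$depth[i]) - 1L, tp)
      data.frame(gene_id = gene$gene_id, category = planted$category[i],
                 chrom = gene$chrom, start = iv[1], end = iv[2],
                 detect_start = if (geo$direction == 1L) iv[1] else iv[1] + sub,
                 detect_end = if (geo$direction == 1L) iv[2] - sub else iv[2],
                 strand = geo$signal, depth = planted$depth[i],
                 anchor = geo$anchor, direction = geo$direction,
                 condition_specific = isTRUE(planted$condition_specific[i]),
                 stringsAsFactors = FALSE)
    }))
  }
  ref_cond <- scenario$samples$conditions[1]
  covs <- list()
  for (j in seq_len(nrow(design))) {
    sm <- design[j, ]
    runs <- list()
    add_run <- function(chrom, strand, start, end, depth) {
      runs[[chrom]][[strand]] <<- rbind(runs[[chrom]][[strand]],
        data.frame(start = start, end = end, depth = depth))
    }
    for (i in seq_len(nrow(genome$genes))) {
      g <- genome$genes[i, ]
      add_run(g$chrom, g$strand, g$start, g$end, scenario$baseline_depth)
    }
    if (!is.null(truth)) for (i in seq_len(nrow(truth))) {
      tr <- truth[i, ]
      if (tr$condition_specific && sm$condition == ref_cond) next
      dep <- tr$depth *
        if (sm$fraction == "IP" && sm$condition != ref_cond) scenario$ip_boost else 1
      # linear taper over the distal `taper` bases, 1-bp runs
      tp <- min(scenario$taper, tr$end - tr$start)
      if (tr$direction == 1L) {
        if (tr$end - tp > tr$start)
          add_run(tr$chrom, tr$strand, tr$start, tr$end - tp, dep)
        b <- (tr$end - tp):(tr$end - 1L)
        add_run(tr$chrom, tr$strand, b, b + 1L, dep * (tr$end - b) / (tp + 1))
      } else {
        if (tr$end > tr$start + tp)
          add_run(tr$chrom, tr$strand, tr$start + tp, tr$end, dep)
        b <- tr$start:(tr$start + tp - 1L)
        add_run(tr$chrom, tr$strand, b, b + 1L, dep * (b - tr$start + 1) / (tp + 1))
      }
    }
    # collapse possibly-overlapping planted/gene runs by per-base max
    runs <- .merge_runs_max(runs, scenario$chrom_length)
    cov <- stranded_coverage(runs, stats::setNames(
      rep(scenario$chrom_length, scenario$n_chroms),
      paste0("chr", utils::as.roman(seq_len(scenario$n_chroms)))))
    if (scenario$noise == "poisson") {
      cov <- .poissonize(cov, .substream_seed(scenario$seed, paste0("noise_", sm$sample_id)))
    }
    covs[[sm$sample_id]] <- cov
  }
  list(coverage = covs, truth = truth, design = design)
}

# overlay runs by per-base maximum (planted regions may touch gene edges)
.merge_runs_max <- function(runs, chrom_length) {
  for (chrom in names(runs)) for (strand in names(runs[[chrom]])) {
    df <- runs[[chrom]][[strand]]
    if (is.null(df) || nrow(df) <= 1) next
    cuts <- sort(unique(c(df$start, df$end)))
    if (length(cuts) < 2) next
    s <- cuts[-length(cuts)]; e <- cuts[-1]
    depth <- vapply(seq_along(s), function(i) {
      hit <- df$start <= s[i] & df$end >= e[i]
      if (any(hit)) max(df$depth[hit]) else 0
    }, 0)
    runs[[chrom]][[strand]] <- data.frame(start = s, end = e, depth = depth)
  }
  runs
}

.poissonize <- function(cov, seed, chunk = 50L) {
  withr::with_seed(seed, {
    for (chrom in names(cov$runs)) for (strand in names(cov$runs[[chrom]])) {
      r <- .runs_of(cov, chrom, strand)
      if (nrow(r) == 0) next
      out <- list()
      for (i in seq_len(nrow(r))) {
        s <- seq(r$start[i], r$end[i] - 1L, by = chunk)
        e <- pmin(s + chunk, r$end[i])
        out[[i]] <- data.frame(start = s, end = e,
                               depth = stats::rpois(length(s), r$depth[i]))
      }
      cov$runs[[chrom]][[strand]] <-
        .canonicalize_runs(do.call(rbind, out), cov$chrom_lengths[[chrom]], chrom)
    }
    cov
  })
}

.scenario_design <- function(scenario) {
  conds <- scenario$samples$conditions
  n <- scenario$samples$n_per_cell
  grid <- expand.grid(replicate = seq_len(n), fraction = c("input", "IP"),
                      condition = conds, stringsAsFactors = FALSE)
  grid$sample_id <- sprintf("%s_%s_r%d", grid$condition, grid$fraction, grid$replicate)
  grid[, c("sample_id", "condition", "fraction", "replicate")]
}

#' Generate an NB count matrix with planted IP enrichment
#'
#' Counts follow `NB(mean = s_j * q_f * 2^(design effects), dispersion)`
#' where the only non-zero design effect is the condition-by-fraction
#' interaction planted on a subset of features — the generative model the
#' enrichment engine assumes, so estimator calibration can be scored
#' against exact truth.
#'
#' @param scenario A [dog_scenario()].
#' @param feature_ids Ids for the simulated features.
#' @param planted_ids Features receiving the interaction effect
#'   (default: first `nb$prop_planted` fraction of `feature_ids`).
#' @return List with `counts`, `design`, `truth` (per-feature true
#'   interaction log2FC), `size_factors` (the true generative factors).
#' @export
make_counts <- function(scenario, feature_ids,
                        planted_ids = NULL) {
  design <- .scenario_design(scenario)
  nb <- scenario$nb
  if (is.null(planted_ids))
    planted_ids <- feature_ids[seq_len(ceiling(length(feature_ids) * (nb$prop_planted %||% 0)))]
  withr::with_seed(.substream_seed(scenario$seed, "counts"), {
    nfeat <- length(feature_ids); nsamp <- nrow(design)
    q <- stats::rlnorm(nfeat, meanlog = log(nb$baseline_mean), sdlog = 0.7)
    s <- rep(1, nsamp)
    if (!is.null(nb$size_factor_range))
      s <- stats::runif(nsamp, nb$size_factor_range[1], nb$size_factor_range[2])
    truth_fc <- ifelse(feature_ids %in% planted_ids, nb$log2fc, 0)
    is_cond <- design$condition != scenario$samples$conditions[1]
    is_ip <- design$fraction == "IP"
    counts <- matrix(0L, nfeat, nsamp,
                     dimnames = list(feature_ids, design$sample_id))
    for (j in seq_len(nsamp)) {
      lfc <- if (is_cond[j] && is_ip[j]) truth_fc else 0
      mu <- s[j] * q * 2^lfc
      counts[, j] <- stats::rnbinom(nfeat, size = 1 / nb$dispersion, mu = mu)
    }
    list(counts = counts, design = design,
         truth = data.frame(feature_id = feature_ids, log2fc = truth_fc,
                            stringsAsFactors = FALSE),
         size_factors = stats::setNames(s, design$sample_id))
  })
}

#' Write a scenario to disk as the pipeline's input files
#'
#' Emits GTF (+ operon features), chrom.sizes, per-sample plus/minus
#' bedGraph pairs, a counts TSV, a sample sheet TSV and truth tables.
#'
#' @param scenario A [dog_scenario()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of file paths.
#' @export
write_scenario_files <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- make_genome(scenario)
  covset <- make_coverage(scenario, genome)
  paths <- list()
  gtf <- file.path(dir, "annotation.gtf")
  .write_gene_gtf(genome$genes, genome$operons, gtf)
  paths$gtf <- gtf
  cs <- file.path(dir, "chrom.sizes")
  utils::write.table(data.frame(names(genome$chrom_lengths), genome$chrom_lengths),
                     cs, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  paths$chrom_sizes <- cs
  sheet <- covset$design
  sheet$plus_bedgraph <- file.path(dir, paste0(sheet$sample_id, ".plus.bedgraph"))
  sheet$minus_bedgraph <- file.path(dir, paste0(sheet$sample_id, ".minus.bedgraph"))
  for (j in seq_len(nrow(sheet))) {
    cov <- covset$coverage[[sheet$sample_id[j]]]
    write_bedgraph(cov, "+", sheet$plus_bedgraph[j])
    write_bedgraph(cov, "-", sheet$minus_bedgraph[j])
  }
  total_bases <- vapply(covset$coverage, function(cov) {
    sum(vapply(names(cov$chrom_lengths), function(ch)
      sum(vapply(.strands, function(st) {
        r <- .runs_of(cov, ch, st); sum((r$end - r$start) * r$depth)
      }, 0)), 0))
  }, 0)
  sheet$total_mapped <- as.integer(round(total_bases / scenario$read_length))
  sheet$rrna_mapped <- 0L
  sheet$read_length <- scenario$read_length
  ss <- file.path(dir, "samples.tsv")
  utils::write.table(sheet, ss, sep = "\t", quote = FALSE, row.names = FALSE)
  paths$sample_sheet <- ss
  if (!is.null(covset$truth)) {
    tt <- file.path(dir, "truth_regions.tsv")
    utils::write.table(covset$truth, tt, sep = "\t", quote = FALSE, row.names = FALSE)
    paths$truth_regions <- tt
  }
  cm <- make_counts(scenario, genome$genes$gene_id)
  ct <- file.path(dir, "counts.tsv")
  utils::write.table(data.frame(feature_id = rownames(cm$counts), cm$counts),
                     ct, sep = "\t", quote = FALSE, row.names = FALSE)
  paths$counts <- ct
  tf <- file.path(dir, "truth_log2fc.tsv")
  utils::write.table(cm$truth, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  paths$truth_log2fc <- tf
  invisible(paths)
}

.write_gene_gtf <- function(genes, operons, path) {
  recs <- data.frame(chrom = genes$chrom, source = "dogcatchr_sim",
                     feature = "gene", start = genes$start + 1L, end = genes$end,
                     score = ".", strand = genes$strand, frame = ".",
                     attrs = sprintf('gene_id "%s"; biotype "%s";',
                                     genes$gene_id, genes$biotype),
                     stringsAsFactors = FALSE)
  if (!is.null(operons) && nrow(operons) > 0) {
    recs <- rbind(recs, data.frame(
      chrom = operons$chrom, source = "dogcatchr_sim", feature = "operon",
      start = operons$start + 1L, end = operons$end, score = ".",
      strand = operons$strand, frame = ".",
      attrs = sprintf('gene_id "%s"; biotype "operon";', operons$operon_id),
      stringsAsFactors = FALSE))
  }
  utils::write.table(recs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
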