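#' Assemble and validate a pipeline configuration
#'
#' @param gtf Gene annotation GTF.
#' @param sample_sheet Sample sheet TSV (`sample_id`, `condition`,
#'   `fraction`, `replicate`, `plus_bedgraph`, `minus_bedgraph`,
#'   `total_mapped`, `rrna_mapped`, `read_length`).
#' @param chrom_sizes Two-column chrom/length TSV.
#' @param out_dir Output directory.
#' @param contrast `c(condition, reference)`.
#' @param operons Optional operon GTF/BED.
#' @param params A [discovery_params()] list.
#' @param categories Region categories to call.
#' @param alpha,min_log2mean Significance thresholds.
#' @param seed Integer seed for any stochastic stage.
#' @param config_yaml Optional YAML file whose entries seed the
#'   configuration; explicit arguments override it.
#' @return A validated list of class `RunConfig`.
#' @export
run_config <- function(gtf, sample_sheet, chrom_sizes, out_dir, contrast,
                       operons = NULL, params = discovery_params(),
                       categories = c("DoG", "ADoG", "PoG", "APoG"),
                       alpha = 0.05, min_log2mean = 4, seed = 1L,
                       config_yaml = NULL) {
  cfg <- list()
  if (!is.null(config_yaml)) cfg <- yaml::read_yaml(config_yaml)
  override <- list(gtf = gtf, sample_sheet = sample_sheet,
                   chrom_sizes = chrom_sizes, out_dir = out_dir,
                   contrast = contrast, operons = operons, params = params,
                   categories = categories, alpha = alpha,
                   min_log2mean = min_log2mean, seed = seed)
  for (nm in names(override)) if (!is.null(override[[nm]])) cfg[[nm]] <- override[[nm]]
  for (nm in c("gtf", "sample_sheet", "chrom_sizes"))
    .assert(file.exists(cfg[[nm]]), "%s not found: %s", nm, cfg[[nm]])
  if (!is.null(cfg$operons))
    .assert(file.exists(cfg$operons), "operons not found: %s", cfg$operons)
  .assert(length(cfg$contrast) == 2, "contrast must be c(condition, reference)")
  if (!inherits(cfg$params, "DiscoveryParams")) cfg$params <- do.call(discovery_params, cfg$params)
  structure(cfg, class = "RunConfig")
}

#' Merge per-sample regions of one contrast into a union set
#'
#' A region enters the tested universe when it is called in at least one
#' sample of the contrast; overlapping same-category, same-strand calls
#' are merged and the union span is tested. Per-sample calls are kept as
#' an audit table.
#'
#' @param region_tables Named list (by sample) of region `data.frame`s.
#' @return Union region `data.frame` with a `members` column listing the
#'   contributing per-sample region ids.
#' @export
union_regions <- function(region_tables) {
  all <- do.call(rbind, lapply(names(region_tables), function(sm) {
    df <- region_tables[[sm]]
    if (is.null(df) || nrow(df) == 0) return(NULL)
    df$sample_id <- sm
    df
  }))
  if (is.null(all)) return(cbind(.empty_region_df(), members = character()))
  out <- list()
  for (key in unique(paste(all$category, all$chrom, all$strand))) {
    a <- all[paste(all$category, all$chrom, all$strand) == key, , drop = FALSE]
    a <- a[order(a$start, a$end), , drop = FALSE]
    cm <- cummax(a$end)
    grp <- cumsum(c(TRUE, a$start[-1] >= cm[-nrow(a)]))
    for (b in split(seq_len(nrow(a)), grp)) {
      ids <- sort(unique(a$region_id[b]))
      r <- a[b[1], ]
      out[[length(out) + 1L]] <- data.frame(
        region_id = ids[1], category = r$category,
        parent_block = paste(sort(unique(a$parent_block[b])), collapse = ";"),
        chrom = r$chrom, start = min(a$start[b]), end = max(a$end[b]),
        strand = r$strand, mode = r$mode,
        mean_depth = max(a$mean_depth[b]),
        skipped_gene_ids = paste(setdiff(unique(unlist(
          strsplit(a$skipped_gene_ids[b], ","))), ""), collapse = ","),
        members = paste(unique(sprintf("%s@%s", a$region_id[b], a$sample_id[b])),
                        collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out[order(out$category, out$chrom, out$start), , drop = FALSE]
}

#' Run the full read-through discovery and enrichment pipeline
#'
#' Stages: parse annotation, flatten, per-sample discovery and filtering,
#' cross-sample union, coverage-based counting of regions and genes,
#' padded NB-LRT enrichment for the configured contrast, significance
#' classification, and the overlapped-gene report. Every output file is
#' listed in a manifest with its md5 checksum.
#'
#' @param config A [run_config()] object.
#' @return Invisibly, a list with `manifest`, `regions`, `results`,
#'   `overlapped_genes`.
#' @export
run_pipeline <- function(config) {
  .assert(inherits(config, "RunConfig"), "config must come from run_config()")
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  log <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", sep = "", file = logf, append = TRUE)
    message(msg)
  }
  cat("", file = logf)
  log("dogcatchr pipeline | seed=%d | contrast=%s vs %s",
      config$seed, config$contrast[1], config$contrast[2])
  yaml::write_yaml(.serializable_config(config), file.path(out_dir, "config.yaml"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  genes <- stage("annotation", parse_gtf(config$gtf))
  operons <- if (!is.null(config$operons))
    stage("annotation", parse_operons(config$operons)) else NULL
  blocks <- stage("flatten", flatten_genes(genes))
  chrom_lengths <- stage("annotation", read_chrom_sizes(config$chrom_sizes))
  sheet <- utils::read.table(config$sample_sheet, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  keep <- sheet$condition %in% config$contrast
  sheet <- sheet[keep, , drop = FALSE]
  .assert(nrow(sheet) > 0, "no samples match the contrast")
  log("annotation: %d genes, %d blocks; %d samples in contrast",
      nrow(genes), nrow(blocks), nrow(sheet))

  per_sample <- list(); removal_logs <- list()
  covs <- list()
  for (j in seq_len(nrow(sheet))) {
    sm <- sheet[j, ]
    cov <- stage("coverage", load_bedgraph_pair(sm$plus_bedgraph, sm$minus_bedgraph,
                                                chrom_lengths))
    covs[[sm$sample_id]] <- cov
    regions <- stage("discovery",
                     discover_all_categories(cov, blocks, genes, config$params,
                                             config$categories))
    filt <- stage("filtering", filter_regions(regions, genes, operons))
    per_sample[[sm$sample_id]] <- filt$regions
    if (nrow(filt$removed)) {
      filt$removed$sample_id <- sm$sample_id
      removal_logs[[sm$sample_id]] <- filt$removed
      for (k in seq_len(nrow(filt$removed)))
        log("WARN [%s] removed %s (rule %s)", sm$sample_id,
            filt$removed$region_id[k], filt$removed$rule[k])
    }
    log("sample %s: %d regions kept, %d removed", sm$sample_id,
        nrow(filt$regions), nrow(filt$removed))
  }

  union <- stage("union", union_regions(per_sample))
  paths <- character()
  emit <- function(name, writer) {
    p <- file.path(out_dir, name); writer(p); paths <<- c(paths, p); p
  }
  for (sm in names(per_sample))
    emit(sprintf("regions_%s.tsv", sm),
         function(p) write_regions(per_sample[[sm]], p, "table"))
  removed_all <- if (length(removal_logs)) do.call(rbind, removal_logs)
                 else data.frame(region_id = character(), rule = character(),
                                 detail = character(), sample_id = character())
  emit("removed_regions.tsv", function(p)
    utils::write.table(removed_all, p, sep = "\t", quote = FALSE, row.names = FALSE))
  emit("regions_union.tsv", function(p)
    utils::write.table(union, p, sep = "\t", quote = FALSE, row.names = FALSE))
  for (fmt in c("bed", "gtf"))
    emit(paste0("regions_union.", fmt),
         function(p) write_regions(union, p, fmt))

  # counting: union regions + all genes, per sample, from coverage
  count_mat <- function(features) {
    m <- vapply(sheet$sample_id, function(sm)
      count_features(covs[[sm]], features, sheet$read_length[sheet$sample_id == sm][1]),
      numeric(max(nrow(features), 0)))
    m <- matrix(m, nrow = nrow(features),
                dimnames = list(features[[intersect(c("gene_id", "region_id"),
                                                    names(features))[1]]],
                                sheet$sample_id))
    m
  }
  region_counts <- stage("counting", if (nrow(union)) count_mat(union) else
    matrix(0, 0, nrow(sheet), dimnames = list(NULL, sheet$sample_id)))
  gene_counts <- stage("counting", count_mat(genes))
  emit("counts_regions.tsv", function(p)
    utils::write.table(data.frame(feature_id = rownames(region_counts), region_counts,
                                  check.names = FALSE),
                       p, sep = "\t", quote = FALSE, row.names = FALSE))
  emit("counts_genes.tsv", function(p)
    utils::write.table(data.frame(feature_id = rownames(gene_counts), gene_counts,
                                  check.names = FALSE),
                       p, sep = "\t", quote = FALSE, row.names = FALSE))

  stats <- sheet[, c("sample_id", "total_mapped", "rrna_mapped")]
  results <- stage("enrichment",
                   padded_lrt(region_counts, gene_counts, sheet, config$contrast,
                              stats = stats, alpha = config$alpha,
                              min_log2mean = config$min_log2mean))
  emit("enrichment_regions.tsv", function(p)
    utils::write.table(results, p, sep = "\t", quote = FALSE, row.names = FALSE))
  log("enrichment: %d regions tested, %d enriched, %d depleted",
      sum(results$tested), sum(results$class == "enriched"),
      sum(results$class == "depleted"))

  dogs <- union[union$category == "DoG", , drop = FALSE]
  adogs <- union[union$category == "ADoG", , drop = FALSE]
  overlapped <- stage("overlap", associate_overlapped_genes(genes, dogs, adogs))
  emit("overlapped_genes.tsv", function(p)
    utils::write.table(overlapped, p, sep = "\t", quote = FALSE, row.names = FALSE))

  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log("wrote %d output files", nrow(manifest))
  invisible(list(manifest = manifest, regions = union, results = results,
                 overlapped_genes = overlapped, per_sample = per_sample))
}

.serializable_config <- function(config) {
  cfg <- unclass(config)
  cfg$params <- unclass(cfg$params)
  cfg
}
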