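chrlen20k <- c(chrI = 20000L)

cov_with <- function(plus = NULL, minus = NULL, len = 20000L) {
  stranded_coverage(list(chrI = list(`+` = plus, `-` = minus)), c(chrI = len))
}

no_blockers <- data.frame(gene_id = character(), start = integer(), end = integer())

test_that("scan extends over covered windows and trims to last covered base", {
  cov <- cov_with(plus = data.frame(start = 1000, end = 1500, depth = 10))
  r <- scan_from_anchor(cov, "chrI", 1000L, 1L, "+", no_blockers, discovery_params())
  expect_equal(c(r$start, r$end), c(1000L, 1500L))
  expect_equal(r$mean_depth, 10)
  # all-zero coverage: first window fails
  expect_null(scan_from_anchor(cov, "chrI", 5000L, 1L, "+", no_blockers,
                               discovery_params()))
})

test_that("local mode truncates at a blocking gene's proximal edge", {
  cov <- cov_with(plus = data.frame(start = 1000, end = 2000, depth = 10))
  blk <- data.frame(gene_id = "gB", start = 1300L, end = 1400L)
  r <- scan_from_anchor(cov, "chrI", 1000L, 1L, "+", blk,
                        discovery_params(mode = "local"))
  expect_equal(c(r$start, r$end), c(1000L, 1300L))
})

test_that("meta mode scans through blocking genes and records them", {
  cov <- cov_with(plus = data.frame(start = 1000, end = 2000, depth = 10))
  blk <- data.frame(gene_id = "gB", start = 1300L, end = 1400L)
  r <- scan_from_anchor(cov, "chrI", 1000L, 1L, "+", blk,
                        discovery_params(mode = "meta"))
  expect_equal(c(r$start, r$end), c(1000L, 2000L))
  expect_equal(r$skipped_gene_ids, "gB")
  # skipped-gene bases are excluded from the mean
  expect_equal(r$mean_depth, 10)
})

test_that("scan agrees with the per-base oracle on random fixtures", {
  params_list <- list(discovery_params(max_extent = 5000),
                      discovery_params(mode = "meta", max_extent = 5000),
                      discovery_params(criterion = "mean", max_extent = 5000))
  for (seed in 1:10) {
    cov <- random_coverage(seed = seed)
    dense <- dense_depth(cov, "chrI", "+", 20000)
    blk <- random_genes(3, seed = seed + 50)[, c("gene_id", "start", "end")]
    set.seed(seed)
    for (params in params_list) {
      for (rep in 1:5) {
        anchor <- sample.int(19000, 1)
        dir <- sample(c(1L, -1L), 1)
        got <- scan_from_anchor(cov, "chrI", anchor, dir, "+", blk, params)
        want <- oracle_scan(dense, anchor, dir, blk, params, 20000)
        if (is.null(want)) expect_null(got)
        else {
          expect_equal(c(got$start, got$end), c(want$start, want$end))
          expect_equal(sort(strsplit(got$skipped_gene_ids, ",")[[1]]), want$skipped)
        }
      }
    }
  }
})

test_that("lowering the depth or coverage-fraction threshold never shortens a region", {
  for (seed in 1:5) {
    cov <- random_coverage(seed = seed, max_depth = 8)
    base <- discovery_params(min_depth = 4, min_covered_frac = 0.9,
                             max_extent = 5000)
    softer <- list(discovery_params(min_depth = 2, min_covered_frac = 0.9,
                                    max_extent = 5000),
                   discovery_params(min_depth = 4, min_covered_frac = 0.5,
                                    max_extent = 5000))
    set.seed(seed + 200)
    for (rep in 1:10) {
      anchor <- sample.int(15000, 1)
      r0 <- scan_from_anchor(cov, "chrI", anchor, 1L, "+", no_blockers, base)
      for (p in softer) {
        r1 <- scan_from_anchor(cov, "chrI", anchor, 1L, "+", no_blockers, p)
        if (!is.null(r0)) {
          expect_false(is.null(r1))
          expect_gte(r1$end - r1$start, r0$end - r0$start)
        }
      }
    }
  }
})

test_that("category geometry anchors each region type at the right edge and strand", {
  genes <- data.frame(gene_id = "g1", chrom = "chrI", start = 5000L, end = 7000L,
                      strand = "+", biotype = "x", stringsAsFactors = FALSE)
  blocks <- flatten_genes(genes)
  params <- discovery_params()
  mk <- function(plus = NULL, minus = NULL) cov_with(plus, minus)
  # sense downstream coverage -> DoG, no ADoG
  dog <- discover_regions(mk(plus = data.frame(start = 7000, end = 7800, depth = 5)),
                          blocks, genes, "DoG", params)
  expect_equal(c(dog$start, dog$end), c(7000L, 7800L))
  expect_equal(dog$strand, "+")
  expect_equal(dog$region_id, "dog1")
  # antisense downstream coverage -> ADoG only
  covm <- mk(minus = data.frame(start = 7000, end = 7800, depth = 5))
  expect_equal(nrow(discover_regions(covm, blocks, genes, "DoG", params)), 0)
  adog <- discover_regions(covm, blocks, genes, "ADoG", params)
  expect_equal(c(adog$start, adog$end), c(7000L, 7800L))
  expect_equal(adog$strand, "-")
  expect_equal(adog$region_id, "adog1")
  # upstream sense -> PoG extends leftward from the 5' end
  pog <- discover_regions(mk(plus = data.frame(start = 4200, end = 5000, depth = 5)),
                          blocks, genes, "PoG", params)
  expect_equal(c(pog$start, pog$end), c(4200L, 5000L))
  # minus-strand gene: DoG anchors at the interval start and extends leftward
  gm <- genes; gm$strand <- "-"
  bm <- flatten_genes(gm)
  dm <- discover_regions(mk(minus = data.frame(start = 4200, end = 5000, depth = 5)),
                         bm, gm, "DoG", params)
  expect_equal(c(dm$start, dm$end), c(4200L, 5000L))
  expect_equal(dm$strand, "-")
})

test_that("discovery output is mirror-symmetric under coordinate reversal", {
  L <- 20000L
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chrI",
                      start = c(3000L, 9000L), end = c(5000L, 11000L),
                      strand = c("+", "-"), biotype = "x", stringsAsFactors = FALSE)
  runs_p <- data.frame(start = c(3000, 5000), end = c(5000, 6000), depth = 10)
  runs_m <- data.frame(start = c(8000, 9000), end = c(9000, 11000), depth = 10)
  cov <- cov_with(plus = runs_p, minus = runs_m, len = L)
  params <- discovery_params()
  fwd <- discover_all_categories(cov, flatten_genes(genes), genes, params)
  # mirror: x -> L - x, strands swapped
  mirror_genes <- genes
  mirror_genes$start <- L - genes$end; mirror_genes$end <- L - genes$start
  mirror_genes$strand <- ifelse(genes$strand == "+", "-", "+")
  mir_run <- function(r) data.frame(start = L - rev(r$end), end = L - rev(r$start),
                                    depth = rev(r$depth))
  mcov <- cov_with(plus = mir_run(runs_m), minus = mir_run(runs_p), len = L)
  rev_ <- discover_all_categories(mcov, flatten_genes(mirror_genes),
                                  mirror_genes, params)
  expect_equal(nrow(fwd), nrow(rev_))
  key <- function(df) {
    k <- df[order(df$category, df$start), ]
    paste(k$category, k$start, k$end)
  }
  mirrored_back <- rev_
  mirrored_back$s2 <- L - rev_$end; mirrored_back$e2 <- L - rev_$start
  mirrored_back$start <- mirrored_back$s2; mirrored_back$end <- mirrored_back$e2
  expect_equal(key(fwd), key(mirrored_back))
})

test_that("published filter rules remove operon DoGs and dependent overlaps", {
  regions <- data.frame(
    region_id = c("doA", "doB", "poC", "adoD", "apoE"),
    category = c("DoG", "DoG", "PoG", "ADoG", "APoG"),
    parent_block = c("A", "B", "C", "D", "E"), chrom = "chrI",
    start = c(500L, 3000L, 2900L, 5000L, 7000L),
    end = c(900L, 3500L, 3100L, 5400L, 7300L),
    strand = c("+", "+", "+", "-", "-"), mode = "local", mean_depth = 5,
    skipped_gene_ids = "", stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = "gX", chrom = "chrI", start = 7200L, end = 7600L,
                      strand = "-", biotype = "x", stringsAsFactors = FALSE)
  operons <- data.frame(operon_id = "op1", chrom = "chrI", start = 800L,
                        end = 1200L, strand = "+", stringsAsFactors = FALSE)
  filt <- filter_regions(regions, genes, operons)
  expect_setequal(filt$removed$region_id, c("doA", "poC", "apoE"))
  expect_equal(filt$removed$rule[filt$removed$region_id == "doA"],
               "operon_same_strand")
  expect_equal(filt$removed$rule[filt$removed$region_id == "poC"], "pog_vs_dog")
  expect_equal(filt$removed$rule[filt$removed$region_id == "apoE"],
               "antisense_vs_opposite")
  expect_setequal(filt$regions$region_id, c("doB", "adoD"))
})

test_that("filters agree with an exhaustive set-algebra oracle on random fixtures", {
  for (seed in 1:8) {
    genes <- random_genes(200, chrom_len = 100000, seed = seed)
    set.seed(seed + 1000)
    n <- 60
    regions <- data.frame(
      region_id = sprintf("r%02d", 1:n),
      category = sample(c("DoG", "ADoG", "PoG", "APoG"), n, replace = TRUE),
      parent_block = "p", chrom = "chrI",
      start = sample.int(99000, n), stringsAsFactors = FALSE)
    regions$end <- regions$start + sample(100:1500, n, replace = TRUE)
    regions$strand <- sample(c("+", "-"), n, replace = TRUE)
    regions$mode <- "local"; regions$mean_depth <- 1
    regions$skipped_gene_ids <- ""
    ops <- data.frame(operon_id = sprintf("o%d", 1:10), chrom = "chrI",
                      start = sample.int(99000, 10), stringsAsFactors = FALSE)
    ops$end <- ops$start + sample(200:2000, 10, replace = TRUE)
    ops$strand <- sample(c("+", "-"), 10, replace = TRUE)
    filt <- filter_regions(regions, genes, ops)
    ov <- function(a, b) a$start < b$end & b$start < a$end
    # oracle: recompute the three rules by exhaustive pairwise checks
    dog <- regions[regions$category == "DoG", ]
    bad_dog <- dog$region_id[sapply(seq_len(nrow(dog)), function(i)
      any(ops$strand == dog$strand[i] & ov(dog[i, ], ops)))]
    live_dog <- dog[!dog$region_id %in% bad_dog, ]
    pog <- regions[regions$category == "PoG", ]
    bad_pog <- pog$region_id[sapply(seq_len(nrow(pog)), function(i)
      any(live_dog$strand == pog$strand[i] & ov(pog[i, ], live_dog)))]
    anti <- regions[regions$category %in% c("ADoG", "APoG"), ]
    bad_anti <- anti$region_id[sapply(seq_len(nrow(anti)), function(i)
      any(genes$strand == anti$strand[i] & ov(anti[i, ], genes)) ||
      any(live_dog$strand == anti$strand[i] & ov(anti[i, ], live_dog)))]
    expect_setequal(filt$removed$region_id, c(bad_dog, bad_pog, bad_anti))
    # post-conditions hold exhaustively on the survivors
    surv <- filt$regions
    sdog <- surv[surv$category == "DoG", ]
    for (i in seq_len(nrow(surv))) {
      r <- surv[i, ]
      if (r$category == "DoG")
        expect_false(any(ops$strand == r$strand & ov(r, ops)))
      if (r$category == "PoG")
        expect_false(any(sdog$strand == r$strand & ov(r, sdog)))
      if (r$category %in% c("ADoG", "APoG")) {
        expect_false(any(genes$strand == r$strand & ov(r, genes)))
        expect_false(any(sdog$strand == r$strand & ov(r, sdog)))
      }
    }
  }
})

test_that("overlapped genes are found via ADoG parentage or opposite-strand DoGs", {
  genes <- data.frame(gene_id = c("gA", "gB", "gC"), chrom = "chrI",
                      start = c(1000L, 5000L, 9000L),
                      end = c(2000L, 6000L, 10000L),
                      strand = c("-", "+", "+"), biotype = "x",
                      stringsAsFactors = FALSE)
  dogs <- data.frame(region_id = "doX", category = "DoG", parent_block = "gX",
                     chrom = "chrI", start = 800L, end = 1200L, strand = "+",
                     mode = "local", mean_depth = 2, skipped_gene_ids = "",
                     stringsAsFactors = FALSE)
  adogs <- data.frame(region_id = "adogB", category = "ADoG", parent_block = "gB",
                      chrom = "chrI", start = 6000L, end = 6500L, strand = "-",
                      mode = "local", mean_depth = 2, skipped_gene_ids = "",
                      stringsAsFactors = FALSE)
  got <- associate_overlapped_genes(genes, dogs, adogs)
  expect_setequal(got$gene_id, c("gA", "gB"))
  expect_true(got$via_opposite_dog[got$gene_id == "gA"])   # + DoG into - gene
  expect_true(got$via_adog[got$gene_id == "gB"])           # own ADoG
  # gC: isolated, not overlapped
  expect_false("gC" %in% got$gene_id)
})
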