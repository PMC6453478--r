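---
title: "Calling and testing read-through transcription with dogcatchr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and testing read-through transcription with dogcatchr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dogcatchr)
```

# The problem

Failure of transcription termination — under heat shock, or in mutants of
RNA-binding proteins — lets RNA polymerase run past the polyadenylation
site, producing downstream-of-gene transcripts (DoGs). Read-through on
one strand is antisense to any gene it crosses on the other strand, so
it can create sense/antisense pairs and double-stranded RNA. `dogcatchr`
(1) annotates read-through regions de novo from stranded coverage,
(2) quantifies them, and (3) tests whether they are differentially
enriched in an immunoprecipitated RNA fraction relative to input RNA
between two conditions — the design of a dsRNA RIP-seq experiment with
a stressed and a control population.

All coordinates inside the package are 0-based half-open; conversion to
and from the 1-based closed GTF convention happens only at file
boundaries. This single-convention rule is deliberate: every off-by-one
class of bug then lives in two small I/O functions.

# Discovery model

## Flattening

Overlapping or touching same-strand gene models are merged into maximal
*flat blocks* (`flatten_genes()`). A read-through region anchors at the
edge of the enclosing block, not of an inner nested gene: downstream
transcription of a gene buried inside a longer host gene only becomes
observable past the host's 3′ end. Touching genes (end == next start)
merge because a 0-bp gap is indistinguishable to a coverage scan.

## The window scan

From an anchor (block 3′ end for DoG/ADoG, 5′ end for PoG/APoG; signal
strand equal to the block strand for DoG/PoG, opposite for ADoG/APoG),
`scan_from_anchor()` examines consecutive non-overlapping windows of
`window` bases (default 100) moving away from the block:

* a window **passes** when at least `min_covered_frac` (default 0.8) of
  its bases have depth ≥ `min_depth` (τ, default 1). A mean-depth
  criterion is available (`criterion = "mean"`); the covered-fraction
  default is robust to single-base spikes, which would let one extreme
  base carry an otherwise empty window under a mean rule.
* extension stops at the first failing window, at `max_extent`
  (default 50 kb, a guard against pathological coverage), or where a
  full window no longer fits before the chromosome end;
* a window overlapping a gene on the *signal* strand stops the scan in
  **local** mode — the region is truncated at that gene's proximal edge —
  or counts as passing in **meta** mode, with the gene recorded in
  `skipped_gene_ids`;
* the distal end is trimmed inward to the last base at depth ≥ τ, so a
  region never carries up to `window − 1` trailing uncovered bases.

Non-overlapping stepping (step = window) is the default because it is
deterministic, linear-time, and bounds the distal quantization error by
one window; `step` is a parameter for a sliding variant. An anchor lying
exactly on the chromosome edge yields no region. One region at most is
produced per (block, category); ids are `do`/`ado`/`po`/`apo` + block
name. Skipped-gene bases are excluded from the region's `mean_depth`,
since gene-body coverage reflects the gene's own transcription, not the
read-through being measured.

## Filtering

Three rules run in order (`filter_regions()`), each demanding ≥ 1 bp of
overlap, and every removal is logged with the rule that fired:

1. DoGs overlapping an **operon** on the same strand are removed:
   polycistronic transcription downstream of one operon member is not
   termination failure. Operons are read from a GTF feature type or a
   BED6 file — the source format is this package's choice.
2. PoGs overlapping a surviving same-strand DoG are removed (the
   "upstream" signal is the upstream neighbor's read-through).
3. ADoGs/APoGs overlapping a gene or surviving DoG on their signal
   strand are removed (the antisense signal is explained by the
   opposite-strand feature).

`associate_overlapped_genes()` then reports genes receiving antisense
read-through: genes contained in an ADoG's parent block, or overlapped
by an opposite-strand DoG.

## Counting

Feature counts are estimated from coverage as
`round(depth_sum / read_length)` on the feature's strand (or the
opposite strand for antisense counts). This keeps the package free of
BAM dependencies and exactly testable; externally produced count
matrices are accepted wherever counts are consumed. The estimator is
within ±2% of true read counts on uniform 10k-read fixtures (tested),
but it does not reproduce any particular read-assignment policy of
feature-counting tools (multi-overlap handling, fractional assignment).

# Enrichment model

## Size factors

Two policies, both centered at geometric mean one (to 1e-12, tested):

* **RSR (rRNA subtraction ratio)** — effective depth
  `d_i = total_mapped_i − rrna_mapped_i`, `s_i = d_i / geomean(d)`. Used
  whenever library stats are available; it is the right scaling when
  some libraries (typically the IP) retain rRNA, which would otherwise
  inflate their apparent depth.
* **median-of-ratios** — the classic pseudo-reference estimator on
  features positive in every sample, falling back to RSR (with a
  warning) when no such feature exists.

## The interaction LRT

For each feature the engine fits a negative binomial log-linear model to
the size-factor-normalized counts `y = K/s`:

full: `log mu = b0 + b_cond + b_frac + b_int`, reduced: drop `b_int`,

with the condition reference level first and fraction levels
(input, IP). The LRT statistic `2(l_full − l_reduced)` (computed as the
deviance difference at fixed dispersion) is referred to chi-squared(1);
`log2FC = b_int / ln 2` is the log2 change of the IP/input ratio between
condition and reference.

The model is fit to *normalized counts* rather than raw counts with a
log-size-factor offset. The two parameterizations give the same mean
model, but the normalized-count likelihood has a property we consider a
correctness contract: jointly rescaling one library's counts and its
size factor changes nothing at all (the normalized data are identical),
whereas a raw-count likelihood would reweight that library's
contribution to the fit. The package asserts this invariance to 1e-8 in
its tests; it holds exactly.

## Dispersion

Per feature, a method-of-moments estimate against the four cell means of
the normalized counts: `phi = sum(s2_c − m_c) / sum(m_c^2 − s2_c/n_c)`
over cells c with ≥ 2 replicates (unbiased per-cell variances; the
`−s2/n` term unbiases the squared mean), floored at 1e-8, then shrunk
half-way toward the mean dispersion of the feature's expression decile.
Cells with a single replicate contribute no variance information; if all
cells are singletons the dispersion falls to the floor and the test is
effectively Poisson — a deliberate, anticonservative-in-the-extreme but
well-defined behavior for degenerate designs.

Plugging a noisy dispersion into the LRT is slightly anticonservative:
if the variance estimate carries d effective degrees of freedom, the
squared t-like statistic has mean d/(d−2), not 1. The moment estimate
uses d0 = n − p residual df, and shrinkage with weight w = 0.5 toward a
trend fitted across many features reduces its sampling variance by
(1 − w)², giving d = d0/(1 − w)². The LRT is therefore divided by
d/(d − 2) before the chi-squared lookup — for the 2×2×3 design,
d = 32 and the factor is 1.067. This is a closed-form mean-matching
correction, not a fitted constant. With it, 2000 simulated null features
at dispersion 0.05 give empirical type-I error ≈ 0.05 and a p-value
distribution indistinguishable from uniform (KS), which the test suite
checks.

This engine is deliberately *not* a re-implementation of any published
DE tool: no Cox–Reid adjustment, no fold-change shrinkage. The test
suite cross-checks the sign of significant log2FCs against DESeq2's
interaction LRT (≥ 98% agreement required) as an independent harness.

## Padding, multiple testing, classification

Novel regions are few and biased toward change, so size factors and the
dispersion trend estimated from them alone are unstable. `padded_lrt()`
concatenates the annotated gene counts with the region counts, estimates
normalization and dispersion on the combined matrix, computes the LRT
for everything, then restricts Benjamini–Hochberg correction and
reporting to the regions. Sense and antisense analyses are corrected
separately (each is its own feature universe). Features with zero mean
get `log2Mean = −Inf` and are excluded before BH; non-converged fits
(IRLS tolerance 1e-8, 100 iterations) are flagged and assigned p = 1.

Classification uses the published thresholds: `enriched` iff
FDR < 0.05, `log2Mean > 4`, `log2FC > 0`; `depleted` with negative
`log2FC`; otherwise `ns`. Both thresholds are parameters.

A design caveat the demo makes visible: a region present only in the
non-reference condition has an IP/input ratio of 0/0 in the reference,
so its interaction is unidentifiable and the LRT is correctly ~0. Novel
condition-specific regions are *discovered* and *reported*, but their
enrichment cannot be attributed to the IP rather than to overall
abundance without reference-condition signal.

# Companion statistics

* `antisense_sense_analysis()` — per-gene
  `log2[(anti+c)/(sense+c)]` change between conditions, pseudocount
  c = 1 (genes with zero sense counts exist), scored only for genes with
  pooled mean count ≥ 20 across the four group means. "Up" tallies use
  strict inequality, so ties count as not-up.
* `hypergeom_overlap()` — upper-tail `P(X ≥ k)` for the overlap of two
  sets in a universe. The universe matters more than anything else in
  this test; the package makes it an explicit argument and the pipeline
  uses the intersection of features scored in both contrasts. Exactness
  is tested against complete enumeration for N ≤ 12 and against
  resampling for larger instances.
* `repeat_enrichment()` — observed count of regions overlapping ≥ 1
  repeat vs a null of length-matched intervals placed uniformly within
  allowed background intervals on the same chromosome;
  `p = (1 + #{null ≥ obs}) / (1 + n_shuffles)`, so p is never 0 and the
  same seed is bit-reproducible.

# The synthetic test bed

`dog_scenario()` + `make_genome()`/`make_coverage()`/`make_counts()`
generate annotation, per-sample stranded coverage, and NB count matrices
with known truth. All randomness flows from one seed, split into named
substreams so each output is independently reproducible; identical seeds
give byte-identical files.

What it emulates: gene bodies at constant depth on their own strand;
planted read-through of chosen category, length and depth, anchored
exactly at the gene edge, decaying linearly to zero over one window at
the distal end; optional condition-specific regions; optional IP-boosted
read-through; NB counts with the engine's generative model (the
interaction effect planted on a subset of features); optional Poisson
coverage noise.

What it does not emulate: spliced alignment artifacts, read-level noise,
mappability gaps, transcription-level correlation between neighboring
genes, or realistic dispersion-mean trends. Passing tests demonstrate
algorithmic correctness against the stated rules and statistical
calibration under the assumed model — not performance on real libraries.

The distal taper is one window long on purpose: boundary recovery would
be trivial with hard edges. Its consequence is that the final
`(taper+1)/depth` bases of a planted region are below τ and invisible to
*any* threshold-based scan, so the generator's truth table records both
the nominal interval and the τ-detectable boundary (`detect_start`/
`detect_end`); boundary-recovery accuracy is scored against the latter,
where the scan guarantees an error below `min_covered_frac × window`
at the distal end and exactly 0 at the anchored end.

# Pipeline and reproducibility

`run_pipeline()` executes: parse → flatten → per-sample discovery →
filtering → cross-sample union (a region is tested when called in ≥ 1
contrast sample; overlapping same-category calls merge to their union
span, and per-sample calls are kept in an audit column) → coverage
counting of regions and genes → padded LRT → classification →
overlapped-gene report. Every output lands in a manifest with md5
checksums, the resolved configuration is serialized beside the outputs,
and re-running with the same seed is checksum-identical (tested). Each
stage is a pure function over files; there is no `--resume-from`
mechanism, since the stages are cheap enough to re-run whole — a known
limitation for very large inputs.

Problem sizes used by the test suite — 200 random 20-kb discovery
fixtures checked base-for-base against a brute-force oracle, 50 planted
recovery scenarios, 2000-feature null calibration, 500 planted-effect
features, 10⁵-draw resampling checks — were chosen as the smallest sizes
at which the checked properties are statistically meaningful.

# Known limitations

* No splice awareness: an intron inside read-through coverage longer
  than `(1 − min_covered_frac) × window` breaks a region in two.
* Unstranded libraries are out of scope; the method is meaningless
  without strand information.
* The coverage-based counter ignores fragment-level effects
  (GC, duplicates) and assigns straddling reads by rounding.
* The log2FC of the 2×2 interaction with 3 replicates per cell has a
  sampling sd of about `sqrt(4(phi + 1/mu)/3)/ln 2` (≈ 0.38 log2 units
  at phi = 0.05) — individual region fold changes are noisy even when
  detection is reliable, and the package reports them unshrunken.
* When two same-strand blocks are separated by less than a region's
  extent, both scans report overlapping regions; no deduplication is
  applied before the explicit union stage, and the removal log plus
  `members` column keep the policy auditable.
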