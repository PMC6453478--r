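#' rRNA-subtraction-ratio (RSR) size factors
#'
#' Libraries that retain rRNA (e.g. IP libraries where rRNA was not
#' depleted) cannot be scaled by total depth. The RSR policy subtracts
#' rRNA-mapped reads from each library's total to get an effective depth,
#' then centers the effective depths at geometric mean one.
#'
#' @param stats `data.frame` with columns `sample_id`, `total_mapped`,
#'   `rrna_mapped`.
#' @return Named numeric vector of size factors; divide raw counts by the
#'   factor to normalize.
#' @export
rsr_size_factors <- function(stats) {
  .assert(all(stats$rrna_mapped >= 0) && all(stats$total_mapped >= stats$rrna_mapped),
          "need 0 <= rrna_mapped <= total_mapped")
  d <- stats$total_mapped - stats$rrna_mapped
  .assert(all(d > 0), "effective depth zero for sample(s): %s",
          paste(stats$sample_id[d == 0], collapse = ", "))
  s <- d / exp(mean(log(d)))
  stats::setNames(s, stats$sample_id)
}

#' Median-of-ratios size factors
#'
#' Classic pseudo-reference normalization: the reference is the per-feature
#' geometric mean over samples (features with a zero anywhere excluded);
#' each sample's factor is its median ratio to the reference, re-centered
#' at geometric mean one.
#'
#' @param counts Integer matrix, features x samples.
#' @param stats Optional library stats; used as an [rsr_size_factors()]
#'   fallback when no feature is positive in every sample.
#' @return Named numeric vector of size factors.
#' @export
median_of_ratios <- function(counts, stats = NULL) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    .assert(!is.null(stats),
            "no feature positive in all samples and no library stats for fallback")
    warning("no all-positive feature; falling back to RSR size factors")
    return(rsr_size_factors(stats)[colnames(counts)])
  }
  lg <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(lg)
  s <- apply(lg, 2, function(col) exp(stats::median(col - ref)))
  s <- s / exp(mean(log(s)))
  stats::setNames(s, colnames(counts))
}

# -- internal NB machinery ---------------------------------------------------

.design_factors <- function(design, contrast) {
  .assert(length(contrast) == 2, "contrast must be c(condition, reference)")
  .assert(all(contrast %in% design$condition),
          "contrast levels absent from design")
  keep <- design$condition %in% contrast
  d <- design[keep, , drop = FALSE]
  .assert(all(d$fraction %in% c("input", "IP")), "fraction must be input/IP")
  cond <- factor(d$condition, levels = c(contrast[2], contrast[1]))
  frac <- factor(d$fraction, levels = c("input", "IP"))
  cells <- table(cond, frac)
  .assert(all(cells >= 1), "each condition x fraction cell needs >= 1 sample")
  list(design = d, cond = cond, frac = frac,
       X_full = stats::model.matrix(~ cond * frac),
       X_red = stats::model.matrix(~ cond + frac))
}

# Per-feature dispersion: method of moments on normalized counts against the
# four cell means, floored, then shrunk half-way toward the mean dispersion
# of the feature's expression decile. Uses unbiased per-cell variances and
# an unbiased estimate of mu^2 (mu_hat^2 - s^2/n_cell) in the denominator.
.dispersion_mom <- function(ynorm, cell, floor = 1e-8) {
  cf <- factor(cell)
  nc <- as.vector(table(cf))
  est <- nc >= 2   # cells with a single replicate carry no variance signal
  phi <- apply(ynorm, 1, function(y) {
    if (!any(est)) return(floor)
    m <- tapply(y, cf, mean)[est]
    s2 <- tapply(y, cf, stats::var)[est]
    num <- sum(s2 - m)
    den <- sum(m^2 - s2 / nc[est])
    num / max(den, floor)
  })
  phi[!is.finite(phi)] <- floor
  pmax(phi, floor)
}

# Small-sample moderation of the plug-in LRT. Estimating the dispersion
# from d0 = n - p residual degrees of freedom and plugging it into the
# likelihood makes the raw LRT slightly anticonservative (E[t^2_d] =
# d/(d-2), not 1). Shrinking the dispersion by weight w toward a trend
# fitted across many features reduces its sampling variance by (1-w)^2,
# giving an effective d = d0/(1-w)^2; dividing the LRT by d/(d-2) before
# the chi-squared(1) lookup mean-matches the reference distribution.
.lrt_moderation <- function(n, p, weight = 0.5) {
  d0 <- max(n - p, 1)
  deff <- d0 / (1 - weight)^2
  if (deff <= 2.5) deff <- 2.5
  deff / (deff - 2)
}

.shrink_dispersion <- function(phi, base_mean, weight = 0.5, n_bins = 10) {
  ok <- base_mean > 0
  out <- phi
  if (sum(ok) >= 2) {
    qs <- unique(stats::quantile(base_mean[ok], probs = seq(0, 1, length.out = n_bins + 1)))
    bin <- cut(base_mean[ok], breaks = qs, include.lowest = TRUE)
    trend <- stats::ave(phi[ok], bin)
    out[ok] <- (1 - weight) * phi[ok] + weight * trend
  }
  out
}

# one NB GLM LRT on normalized counts with fixed dispersion phi.
# Fitting the normalized counts directly (rather than raw counts with a
# log size-factor offset) makes every statistic exactly invariant to
# jointly rescaling a library's counts and its size factor.
.nb_lrt_one <- function(ynorm, X_full, X_red, phi) {
  fam <- MASS::negative.binomial(theta = 1 / phi)
  ctl <- stats::glm.control(epsilon = 1e-8, maxit = 100)
  full <- suppressWarnings(stats::glm.fit(X_full, ynorm, family = fam, control = ctl))
  red <- suppressWarnings(stats::glm.fit(X_red, ynorm, family = fam, control = ctl))
  lrt <- max(red$deviance - full$deviance, 0)
  conv <- isTRUE(full$converged) && isTRUE(red$converged)
  beta_int <- full$coefficients[ncol(X_full)]
  list(lrt = lrt, log2FC = beta_int / log(2), converged = conv)
}

.nb_lrt_core <- function(counts, design, size_factors, contrast) {
  counts <- as.matrix(counts)
  .assert(!is.null(rownames(counts)), "counts must have feature-id rownames")
  df <- .design_factors(design, contrast)
  ids <- df$design$sample_id
  .assert(all(ids %in% colnames(counts)), "design samples absent from counts")
  .assert(all(ids %in% names(size_factors)), "design samples absent from size factors")
  K <- counts[, ids, drop = FALSE]
  s <- size_factors[ids]
  ynorm <- sweep(K, 2, s, "/")
  base_mean <- rowMeans(ynorm)
  cell <- paste(df$cond, df$frac)
  phi <- .dispersion_mom(ynorm, cell)
  phi <- .shrink_dispersion(phi, base_mean)
  moderation <- .lrt_moderation(ncol(K), ncol(df$X_full))
  res <- data.frame(feature_id = rownames(K),
                    log2Mean = ifelse(base_mean > 0, log2(base_mean), -Inf),
                    log2FC = NA_real_, lrt_stat = NA_real_,
                    pvalue = NA_real_, fdr = NA_real_,
                    converged = NA, tested = base_mean > 0,
                    class = "ns", stringsAsFactors = FALSE)
  for (i in which(res$tested)) {
    fit <- .nb_lrt_one(ynorm[i, ], df$X_full, df$X_red, phi[i])
    res$log2FC[i] <- fit$log2FC
    res$converged[i] <- fit$converged
    if (fit$converged) {
      res$lrt_stat[i] <- fit$lrt
      res$pvalue[i] <- stats::pchisq(fit$lrt / moderation, df = 1, lower.tail = FALSE)
    } else {
      res$lrt_stat[i] <- NA_real_
      res$pvalue[i] <- 1    # conservative failure mode
    }
  }
  res$pvalue[!res$tested] <- 1  # all-zero features: ns by construction
  rownames(res) <- NULL
  res
}

.apply_bh <- function(res, subset = res$tested) {
  res$fdr <- NA_real_
  res$fdr[subset] <- stats::p.adjust(res$pvalue[subset], method = "BH")
  res
}

#' NB likelihood-ratio test for IP-vs-input enrichment
#'
#' Per feature, fits a negative binomial log-linear model with condition,
#' fraction (input/IP) and their interaction, against a reduced model
#' without the interaction. The interaction coefficient is the log fold
#' change of the IP/input ratio between the two conditions — the
#' enrichment of the feature in the IP pool relative to the reference —
#' and the likelihood-ratio statistic is referred to chi-squared with one
#' degree of freedom. Dispersion is estimated per feature by method of
#' moments on normalized counts and shrunk toward its expression-decile
#' trend. Benjamini-Hochberg correction is applied across tested features
#' and the paper-style significance classes are assigned.
#'
#' @param counts Integer matrix (features x samples) with rownames.
#' @param design `data.frame` with `sample_id`, `condition`, `fraction`
#'   (`"input"`/`"IP"`), `replicate`.
#' @param size_factors Named vector from [rsr_size_factors()] or
#'   [median_of_ratios()].
#' @param contrast `c(condition, reference)` — exactly two conditions.
#' @param alpha,min_log2mean Classification thresholds (see
#'   [classify_enrichment()]).
#' @return `data.frame` with `feature_id`, `log2Mean`, `log2FC`,
#'   `lrt_stat`, `pvalue`, `fdr`, `converged`, `tested`, `class`.
#' @export
nb_lrt_enrichment <- function(counts, design, size_factors, contrast,
                              alpha = 0.05, min_log2mean = 4) {
  res <- .nb_lrt_core(counts, design, size_factors, contrast)
  res <- .apply_bh(res)
  classify_enrichment(res, alpha = alpha, min_log2mean = min_log2mean)
}

#' Padded enrichment test for read-through regions
#'
#' Novel regions alone are a small, biased feature set: size factors and
#' the dispersion trend estimated from them are unstable. Padding
#' concatenates the annotated gene counts with the region counts so that
#' normalization and dispersion shrinkage see the stable gene background,
#' computes the LRT for everything, then restricts multiple-testing
#' correction and reporting to the regions.
#'
#' @param target_counts Region x sample count matrix (rownames = ids).
#' @param gene_counts Gene x sample count matrix from the same samples.
#' @param design,contrast As in [nb_lrt_enrichment()].
#' @param stats Optional library stats; if given, RSR size factors are
#'   used, otherwise median-of-ratios on the padded matrix.
#' @param alpha,min_log2mean Classification thresholds.
#' @return Results for the target features only.
#' @export
padded_lrt <- function(target_counts, gene_counts, design, contrast,
                       stats = NULL, alpha = 0.05, min_log2mean = 4) {
  target_counts <- as.matrix(target_counts); gene_counts <- as.matrix(gene_counts)
  clash <- intersect(rownames(target_counts), rownames(gene_counts))
  .assert(length(clash) == 0, "feature-id collision between targets and genes: %s",
          paste(utils::head(clash, 5), collapse = ", "))
  if (nrow(target_counts) == 0) {
    out <- .nb_lrt_core(gene_counts, design, median_of_ratios(gene_counts, stats),
                        contrast)[0, ]
    out$class <- character(0)
    return(out)
  }
  combined <- rbind(gene_counts, target_counts)
  sf <- if (!is.null(stats)) rsr_size_factors(stats) else median_of_ratios(combined)
  res <- .nb_lrt_core(combined, design, sf, contrast)
  is_target <- res$feature_id %in% rownames(target_counts)
  res <- .apply_bh(res, subset = is_target & res$tested)
  res <- res[is_target, , drop = FALSE]
  rownames(res) <- NULL
  classify_enrichment(res, alpha = alpha, min_log2mean = min_log2mean)
}

#' Significance classification at the published thresholds
#'
#' A feature is `enriched` when `fdr < alpha`, `log2Mean > min_log2mean`
#' and `log2FC > 0`; `depleted` with `log2FC < 0`; otherwise `ns`. The
#' defaults are the published FDR < 0.05 and log2 mean expression > 4.
#'
#' @param results Output of [nb_lrt_enrichment()] / [padded_lrt()].
#' @param alpha FDR threshold.
#' @param min_log2mean Expression floor on `log2Mean`.
#' @return `results` with the `class` column set.
#' @export
classify_enrichment <- function(results, alpha = 0.05, min_log2mean = 4) {
  cls <- rep("ns", nrow(results))
  ok <- !is.na(results$fdr) & results$fdr < alpha &
        is.finite(results$log2Mean) & results$log2Mean > min_log2mean &
        !is.na(results$log2FC)
  cls[ok & results$log2FC > 0] <- "enriched"
  cls[ok & results$log2FC < 0] <- "depleted"
  results$class <- cls
  results
}
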