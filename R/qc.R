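#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the observed minor-allele count: the
#' p-value is the summed probability of every attainable heterozygote count
#' whose conditional probability does not exceed that of the observed
#' count.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (non-negative).
#' @return Exact p-value in (0, 1].
#' @examples
#' hwe_exact_test(57, 34, 9)
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Genotype counts must be non-negative integers.")
  }
  n <- sum(counts)
  if (n == 0) abort("Total genotype count must be positive.")
  na <- min(2 * n_hom_ref + n_het, 2 * n_hom_alt + n_het) # minor allele count
  if (na == 0) return(1)
  hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  logp <- lfactorial(n) - lfactorial((na - hets) / 2) - lfactorial(hets) -
    lfactorial((2 * n - na - hets) / 2) + hets * log(2) +
    lfactorial(na) + lfactorial(2 * n - na) - lfactorial(2 * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_het, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-9)]))
}

#' @noRd
genotype_counts <- function(dosages) {
  c(sum(dosages == 0, na.rm = TRUE),
    sum(dosages == 1, na.rm = TRUE),
    sum(dosages == 2, na.rm = TRUE))
}

#' Filter samples and variants by genotype call rate
#'
#' Samples are filtered first, then variants, each retained at call rate
#' `>= threshold`.
#'
#' @param geno A [geno_matrix()].
#' @param sample_threshold,variant_threshold Minimum call rate retained,
#'   in (0, 1].
#' @return List with the filtered `genotypes` and a `removed` tibble
#'   (`type`, `id`, `reason`, `call_rate`).
#' @export
call_rate_filter <- function(geno, sample_threshold = 0.95,
                             variant_threshold = 0.95) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (nrow(geno$calls) == 0 || ncol(geno$calls) == 0) {
    abort("Empty genotype matrix.")
  }
  stopifnot(sample_threshold > 0, sample_threshold <= 1,
            variant_threshold > 0, variant_threshold <= 1)
  s_rate <- rowMeans(!is.na(geno$calls))
  keep_s <- s_rate >= sample_threshold
  removed <- tibble(type = "sample", id = rownames(geno$calls)[!keep_s],
                    reason = "call_rate", call_rate = s_rate[!keep_s])
  g2 <- geno[which(keep_s), ]
  v_rate <- colMeans(!is.na(g2$calls))
  keep_v <- v_rate >= variant_threshold
  removed <- bind_rows(removed, tibble(
    type = "variant", id = colnames(g2$calls)[!keep_v],
    reason = "call_rate", call_rate = v_rate[!keep_v]))
  list(genotypes = g2[, which(keep_v)], removed = removed)
}

#' Filter variants deviating from HWE in a reference stratum
#'
#' Variants with exact HWE p-value below `alpha`, computed within the
#' samples of one ethnicity stratum (cases and controls combined), are
#' removed. Testing within a single genetically homogeneous stratum avoids
#' spurious HWE failures caused by population mixture.
#'
#' @param geno A [geno_matrix()].
#' @param samples Sample sheet tibble (`sample_id`, `ethnicity`).
#' @param stratum Ethnicity label of the reference stratum.
#' @param alpha Removal threshold on the HWE p-value.
#' @return List with filtered `genotypes` and a `removed` tibble
#'   (`id`, `hwe_p`).
#' @export
hwe_filter <- function(geno, samples, stratum = "Chinese", alpha = 1e-6) {
  ids <- samples$sample_id[samples$ethnicity == stratum]
  ids <- intersect(ids, rownames(geno$calls))
  if (length(ids) < 2) abort(sprintf("Stratum %s has fewer than 2 samples.", stratum))
  sub <- geno$calls[ids, , drop = FALSE]
  p <- vapply(seq_len(ncol(sub)), function(j) {
    cnt <- genotype_counts(sub[, j])
    if (sum(cnt) == 0) return(1)
    hwe_exact_test(cnt[1], cnt[2], cnt[3])
  }, numeric(1))
  drop <- p < alpha
  list(genotypes = geno[, which(!drop)],
       removed = tibble(id = colnames(sub)[drop], hwe_p = p[drop]),
       hwe_p = tibble(id = colnames(sub), hwe_p = p))
}

#' Pairwise identity-by-state similarity
#'
#' For each sample pair, the mean over shared non-missing variants of
#' `(2 - |dosage difference|) / 2` (1 = identical genotypes). Pairs at or
#' above `threshold` are flagged as potential duplicates/relatives; pairs
#' with no shared non-missing variants get `NA` similarity.
#'
#' @param geno A [geno_matrix()].
#' @param threshold Flagging threshold (default 0.9).
#' @return Tibble (`sample1`, `sample2`, `ibs`, `n_shared`, `flagged`).
#' @export
pairwise_ibs <- function(geno, threshold = 0.9) {
  stopifnot(inherits(geno, "geno_matrix"))
  m <- geno$calls
  if (nrow(m) < 2) abort("Need at least 2 samples.")
  ids <- rownames(m)
  pairs <- utils::combn(nrow(m), 2)
  res <- apply(pairs, 2, function(ij) {
    d <- abs(m[ij[1], ] - m[ij[2], ])
    ok <- !is.na(d)
    c(ibs = if (any(ok)) mean((2 - d[ok]) / 2) else NA_real_,
      n_shared = sum(ok))
  })
  ibs <- unname(res["ibs", ])
  tibble(
    sample1 = ids[pairs[1, ]], sample2 = ids[pairs[2, ]],
    ibs = ibs, n_shared = as.integer(unname(res["n_shared", ])),
    flagged = !is.na(ibs) & ibs >= threshold
  )
}

#' Flag samples with outlying heterozygosity
#'
#' Per-sample heterozygous fraction over non-missing calls; samples beyond
#' `mean +/- sd_multiplier * SD` are flagged (excess heterozygosity
#' suggests contamination; a deficit suggests inbreeding or genotyping
#' failure).
#'
#' @param geno A [geno_matrix()].
#' @param sd_multiplier Flagging width in standard deviations (default 3).
#' @return Tibble (`sample_id`, `het_frac`, `flagged`).
#' @export
heterozygosity_check <- function(geno, sd_multiplier = 3) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (nrow(geno$calls) < 3) abort("Need at least 3 samples.")
  het <- rowMeans(geno$calls == 1, na.rm = TRUE)
  mu <- mean(het)
  s <- sd(het)
  flag <- if (s == 0) rep(FALSE, length(het)) else abs(het - mu) > sd_multiplier * s
  tibble(sample_id = rownames(geno$calls), het_frac = unname(het),
         flagged = unname(flag))
}

#' Principal components of the genotype matrix
#'
#' Missing dosages are imputed to the per-variant mean, variants are
#' standardized to mean 0 / unit variance (zero-variance variants dropped),
#' and the spectrum of the sample covariance is taken. Components are
#' ordered by eigenvalue; each component's sign is fixed so its
#' largest-magnitude variant loading is positive.
#'
#' @param geno A [geno_matrix()].
#' @param n_components Number of components to keep.
#' @return A `geno_pca` list: `eigenvalues`, `scores` (tibble with
#'   `sample_id`, `PC1`...), `loadings`.
#' @export
genotype_pca <- function(geno, n_components = 10) {
  stopifnot(inherits(geno, "geno_matrix"))
  x <- geno$calls
  storage.mode(x) <- "double"
  mu <- colMeans(x, na.rm = TRUE)
  for (j in which(colSums(is.na(x)) > 0)) x[is.na(x[, j]), j] <- mu[j]
  v <- apply(x, 2, var)
  x <- x[, v > 0, drop = FALSE]
  if (ncol(x) == 0) abort("All variants have zero variance.")
  x <- scale(x)
  k <- min(n_components, nrow(x) - 1, ncol(x))
  if (nrow(x) < k) abort("Fewer retained samples than components.")
  pc <- prcomp(x, center = FALSE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  sco <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  scores <- as_tibble(sco)
  scores <- bind_cols(tibble(sample_id = rownames(geno$calls)), scores)
  structure(list(
    eigenvalues = pc$sdev[seq_len(k)]^2,
    scores = scores,
    loadings = rot
  ), class = "geno_pca")
}

#' @export
print.geno_pca <- function(x, ...) {
  cat(sprintf("<geno_pca> %d components; leading eigenvalues: %s\n",
              length(x$eigenvalues),
              paste(signif(utils::head(x$eigenvalues, 3), 3), collapse = ", ")))
  invisible(x)
}

#' Run the full genotype QC stage
#'
#' Composes, in order: injected sex-mismatch removals (sex inference from
#' array intensities is outside this package, so mismatches discovered
#' upstream are passed in as ids), sample/variant call-rate filtering, HWE
#' filtering within the reference stratum, IBS duplicate detection and
#' heterozygosity outlier detection (flagged samples removed), and PCA on
#' the retained matrix.
#'
#' @param geno A [geno_matrix()].
#' @param samples Sample sheet tibble.
#' @param sample_call_rate,variant_call_rate Call-rate thresholds.
#' @param hwe_stratum,hwe_alpha HWE reference stratum and threshold.
#' @param ibs_threshold IBS flagging threshold.
#' @param het_sd Heterozygosity flagging width (SDs).
#' @param n_pcs Principal components to compute.
#' @param sex_mismatch Character vector of sample ids failing an upstream
#'   sex check.
#' @return A `qc_result` list: retained `genotypes` and `samples`, the
#'   removals `report` tibble, per-variant `hwe_p`, `ibs` table, `het`
#'   table, and `pca`.
#' @export
run_qc <- function(geno, samples,
                   sample_call_rate = 0.95, variant_call_rate = 0.95,
                   hwe_stratum = "Chinese", hwe_alpha = 1e-6,
                   ibs_threshold = 0.9, het_sd = 3, n_pcs = 10,
                   sex_mismatch = character(0)) {
  report <- tibble(type = character(), id = character(), reason = character())
  drop_sex <- intersect(sex_mismatch, rownames(geno$calls))
  if (length(drop_sex)) {
    report <- bind_rows(report, tibble(type = "sample", id = drop_sex,
                                       reason = "sex_mismatch"))
    geno <- geno[setdiff(rownames(geno$calls), drop_sex), ]
  }
  cr <- call_rate_filter(geno, sample_call_rate, variant_call_rate)
  report <- bind_rows(report, cr$removed[, c("type", "id", "reason")])
  hw <- hwe_filter(cr$genotypes, samples, hwe_stratum, hwe_alpha)
  if (nrow(hw$removed)) {
    report <- bind_rows(report, tibble(type = "variant", id = hw$removed$id,
                                       reason = "hwe"))
  }
  g <- hw$genotypes
  ibs <- pairwise_ibs(g, ibs_threshold)
  dup <- unique(ibs$sample2[ibs$flagged])
  het <- heterozygosity_check(g, het_sd)
  out_het <- het$sample_id[het$flagged]
  drop2 <- union(dup, out_het)
  if (length(drop2)) {
    report <- bind_rows(report, tibble(
      type = "sample", id = drop2,
      reason = ifelse(drop2 %in% dup, "high_ibs", "heterozygosity")))
    g <- g[setdiff(rownames(g$calls), drop2), ]
  }
  samples_kept <- samples[samples$sample_id %in% rownames(g$calls), ]
  structure(list(
    genotypes = g, samples = samples_kept, report = report,
    hwe_p = hw$hwe_p, ibs = ibs, het = het,
    pca = genotype_pca(g, n_pcs)
  ), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("<qc_result> retained %d samples x %d variants; %d removals\n",
              nrow(x$genotypes$calls), ncol(x$genotypes$calls),
              nrow(x$report)))
  invisible(x)
}
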