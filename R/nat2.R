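#' Default NAT2 acetylator inference panel
#'
#' The 4-SNP panel used to call acetylator phenotype. Dosage orientation is
#' the count of the acetylation-slowing (variant) allele. rs1801279 is
#' expected monomorphic in Chinese, Malay and Indian populations and is
#' imputed to homozygous wild type when missing.
#'
#' @return Tibble (`id`, `gene`, `counted_allele`, `impute_ref_if_missing`).
#' @export
nat2_panel <- function() {
  tibble(
    id = c("rs1801280", "rs1799930", "rs1799931", "rs1801279"),
    gene = "NAT2",
    counted_allele = c("G", "A", "A", "A"),
    impute_ref_if_missing = c(FALSE, FALSE, FALSE, TRUE)
  )
}

#' Infer NAT2 acetylator phenotype from panel genotypes
#'
#' Rule-based phenotype call from variant-allele dosages at the panel SNPs:
#' rapid (RA) when homozygous common at every panel SNP; intermediate (IA)
#' when heterozygous at exactly one SNP; slow (SA) when heterozygous at two
#' or more SNPs or homozygous variant at any SNP. SA is the DILI-risk
#' exposure class.
#'
#' Missing handling: panel SNPs flagged `impute_ref_if_missing` (by default
#' only rs1801279) are set to dosage 0 with an imputation flag. Under
#' `missing_policy = "default"` any other missing panel SNP refuses the
#' call (`NA` phenotype with a reason); `missing_policy = "strict"` behaves
#' the same but also treats a missing rs1801279 as refusal.
#'
#' @param geno A [geno_matrix()] containing the panel SNPs.
#' @param panel Panel definition as [nat2_panel()].
#' @param missing_policy `"default"` or `"strict"`.
#' @return Tibble of acetylator calls: `sample_id`, per-SNP dosage columns,
#'   `imputed_snps`, `phenotype` (`RA`/`IA`/`SA` or `NA`), `exposure`
#'   (SA vs not), `refused_reason`.
#' @examples
#' cohort <- generate_cohort(sim_config(n_background_snps = 0,
#'                                      missing_rate = 0, seed = 7))
#' calls <- infer_acetylator(cohort$genotypes)
#' table(calls$phenotype)
#' @export
infer_acetylator <- function(geno, panel = nat2_panel(),
                             missing_policy = c("default", "strict")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(geno, "geno_matrix"))
  missing_panel <- setdiff(panel$id, geno$variants$id)
  if (length(missing_panel)) {
    if (!all(panel$impute_ref_if_missing[panel$id %in% missing_panel])) {
      abort(sprintf("Panel SNP(s) absent from matrix: %s",
                    paste(missing_panel, collapse = ", ")))
    }
  }
  # allele orientation check for SNPs present in the matrix
  present <- panel[!panel$id %in% missing_panel, ]
  ori <- geno$variants$counted_allele[match(present$id, geno$variants$id)]
  if (any(ori != present$counted_allele)) {
    bad <- present$id[ori != present$counted_allele]
    abort(sprintf("Counted-allele mismatch for panel SNP(s): %s",
                  paste(bad, collapse = ", ")))
  }
  n <- nrow(geno$calls)
  dos <- matrix(NA_integer_, n, nrow(panel),
                dimnames = list(rownames(geno$calls), panel$id))
  for (id in present$id) dos[, id] <- geno$calls[, id]
  imputed <- matrix(FALSE, n, nrow(panel), dimnames = dimnames(dos))
  strict_all <- missing_policy == "strict"
  for (k in seq_len(nrow(panel))) {
    id <- panel$id[k]
    if (panel$impute_ref_if_missing[k] && !strict_all) {
      miss <- is.na(dos[, id])
      dos[miss, id] <- 0L
      imputed[miss, id] <- TRUE
    }
  }
  n_missing <- rowSums(is.na(dos))
  count_het <- rowSums(dos == 1, na.rm = TRUE)
  any_hom <- rowSums(dos == 2, na.rm = TRUE) > 0
  phen <- rep(NA_character_, n)
  complete <- n_missing == 0
  phen[complete & (any_hom | count_het >= 2)] <- "SA"
  phen[complete & !any_hom & count_het == 1] <- "IA"
  phen[complete & !any_hom & count_het == 0] <- "RA"
  refused <- is.na(phen)
  out <- as_tibble(dos)
  bind_cols(tibble(sample_id = rownames(geno$calls)), out) %>%
    mutate(
      imputed_snps = unname(apply(imputed, 1, function(r)
        paste(panel$id[r], collapse = ","))),
      phenotype = factor(phen, levels = c("RA", "IA", "SA")),
      exposure = .data$phenotype == "SA",
      refused_reason = ifelse(refused, "missing_panel_genotype", NA_character_)
    )
}

#' Classify samples by the rs1495741 tag SNP
#'
#' Maps tag-SNP dosage (counting the G allele) to genotype class and to the
#' predicted phenotype: the AA class (dosage 0) predicts slow acetylator;
#' AG and GG are protective and predict non-SA.
#'
#' @param geno A [geno_matrix()] containing the tag SNP.
#' @param tag Tag SNP id.
#' @return Tibble (`sample_id`, `tag_class`, `predicted_sa`).
#' @export
classify_by_tag <- function(geno, tag = "rs1495741") {
  dos <- dosage_of(geno, tag)
  cls <- c("AA", "AG", "GG")[dos + 1L]
  tibble(
    sample_id = rownames(geno$calls),
    tag_class = ifelse(is.na(cls), "missing", cls),
    predicted_sa = ifelse(is.na(cls), NA, cls == "AA")
  )
}

#' Concordance between tag-SNP class and acetylator phenotype
#'
#' Fraction of samples whose tag-SNP prediction (AA = SA) agrees with the
#' panel-inferred acetylator phenotype. Samples with a missing tag genotype
#' or a refused acetylator call are excluded.
#'
#' @param calls Acetylator calls from [infer_acetylator()].
#' @param tags Tag classes from [classify_by_tag()].
#' @return List with `concordance`, the 2x2 `table`
#'   (tag AA x phenotype SA), and `n` evaluated.
#' @export
tag_concordance <- function(calls, tags) {
  shared <- intersect(calls$sample_id, tags$sample_id)
  if (!length(shared)) abort("No shared sample ids between calls and tags.")
  df <- left_join(calls[, c("sample_id", "exposure")],
                  tags[, c("sample_id", "predicted_sa")], by = "sample_id") %>%
    filter(.data$sample_id %in% shared,
           !is.na(.data$exposure), !is.na(.data$predicted_sa))
  if (!nrow(df)) abort("No evaluable samples (all missing).")
  tab <- table(tag_AA = df$predicted_sa, phenotype_SA = df$exposure)
  list(concordance = mean(df$predicted_sa == df$exposure),
       table = tab, n = nrow(df))
}

#' Risk allele frequency by DILI grade
#'
#' Per grade, the frequency of the designated risk allele of a variant
#' (counting risk alleles over called chromosomes) or, for `exposure =`
#' a logical per-sample vector, the exposed fraction. Grades with no
#' samples are absent from the output rather than reported as zero.
#'
#' @param samples Sample sheet tibble with `sample_id` and `grade`.
#' @param geno Optional [geno_matrix()]; required with `variant`.
#' @param variant Variant id whose counted allele is the risk allele; for
#'   rs1495741 the risk allele is A (the AA genotype is the risk class), so
#'   set `risk_is_counted = FALSE` there.
#' @param exposure Alternatively, a tibble (`sample_id`, `exposure`) such
#'   as SA status; its exposed fraction per grade is reported.
#' @param risk_is_counted Whether the risk allele is the counted allele.
#' @return Tibble (`grade`, `n`, `freq`).
#' @export
risk_allele_freq_by_grade <- function(samples, geno = NULL, variant = NULL,
                                      exposure = NULL,
                                      risk_is_counted = TRUE) {
  if (is.null(variant) == is.null(exposure)) {
    abort("Give exactly one of `variant` or `exposure`.")
  }
  if (!is.null(variant)) {
    dos <- dosage_of(geno, variant)
    if (!risk_is_counted) dos <- 2L - dos
    df <- tibble(sample_id = names(dos), value = as.numeric(dos) / 2)
  } else {
    df <- tibble(sample_id = exposure$sample_id,
                 value = as.numeric(exposure$exposure))
  }
  samples %>%
    left_join(df, by = "sample_id") %>%
    filter(!is.na(.data$value)) %>%
    group_by(grade = .data$grade) %>%
    summarise(n = dplyr::n(), freq = mean(.data$value), .groups = "drop") %>%
    arrange(.data$grade)
}
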