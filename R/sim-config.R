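#' NAT2 panel SNP order used by the simulator
#'
#' The seven common NAT2 coding SNPs, in the column order used by the
#' haplotype definition table.
#' @return Character vector of rs ids.
#' @export
nat2_snps <- function() {
  c("rs1801279", "rs1041983", "rs1801280", "rs1799929",
    "rs1799930", "rs1208", "rs1799931")
}

#' Default NAT2 haplotype table
#'
#' Synthetic stand-in haplotype definitions and frequencies in star-allele
#' style. The haplotype structure follows the canonical NAT2 alleles
#' (*4 reference rapid; *13A rapid carrying only rs1041983; *5B/*5C, *6A,
#' *7B and *14A slow), and the frequencies are calibrated so that the
#' implied marginal minor-allele frequencies match the control-group MAFs
#' of the Singaporean cohort the package emulates (rs1041983 0.367,
#' rs1801280 0.095, rs1799929 0.076, rs1799930 0.222, rs1799931 0.139,
#' rs1801279 monomorphic). No per-ethnicity haplotype frequencies are
#' published for that cohort, so one table is used for every stratum.
#'
#' @return Tibble with columns `haplotype`, `slow`, one 0/1 column per
#'   NAT2 SNP, and `freq`.
#' @export
nat2_haplotypes <- function() {
  snps <- nat2_snps()
  def <- tibble(
    haplotype = c("NAT2*4", "NAT2*13A", "NAT2*5B", "NAT2*5C",
                  "NAT2*6A", "NAT2*7B", "NAT2*14A"),
    slow = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    rs1801279 = c(0L, 0L, 0L, 0L, 0L, 0L, 1L),
    rs1041983 = c(0L, 1L, 0L, 0L, 1L, 1L, 0L),
    rs1801280 = c(0L, 0L, 1L, 1L, 0L, 0L, 0L),
    rs1799929 = c(0L, 0L, 1L, 0L, 0L, 0L, 0L),
    rs1799930 = c(0L, 0L, 0L, 0L, 1L, 0L, 0L),
    rs1208    = c(0L, 0L, 1L, 1L, 0L, 0L, 0L),
    rs1799931 = c(0L, 0L, 0L, 0L, 0L, 1L, 0L),
    freq = c(0.538, 0.006, 0.076, 0.019, 0.222, 0.139, 0)
  )
  stopifnot(abs(sum(def$freq) - 1) < 1e-9, all(snps %in% names(def)))
  def
}

#' Variant annotation for the simulated NAT2 region
#'
#' Chromosome-8 positions (GRCh37-style, approximate) and counted-allele
#' orientation for the 7 NAT2 coding SNPs and the rs1495741 tag SNP. The
#' counted allele is the acetylation-slowing (minor/variant) allele for the
#' coding SNPs and the G allele for the tag SNP, so tag dosage 0 is the AA
#' risk genotype.
#' @return Variant tibble suitable for [geno_matrix()].
#' @export
nat2_variant_table <- function() {
  tibble(
    id = c(nat2_snps(), "rs1495741"),
    chrom = "8",
    pos = c(18257529L, 18257854L, 18257795L, 18258103L, 18258316L,
            18258370L, 18258445L, 18272881L),
    counted_allele = c("A", "A", "G", "A", "A", "G", "A", "G"),
    other_allele  = c("G", "G", "A", "G", "G", "A", "G", "A"),
    gene = c(rep("NAT2", 7), "NAT2-tag")
  ) %>% arrange(.data$pos)
}

#' Build a simulation configuration
#'
#' Defines the generative model for a synthetic INH-DILI case-control
#' cohort: per-stratum sample sizes, NAT2 haplotype frequencies, tag-SNP
#' concordance, background variants with stratum divergence, and the
#' retrospective logistic disease model.
#'
#' Defaults emulate the multi-ethnic Singaporean study cohort: 24 cases and
#' 79 controls split over Chinese (12/57), Malay (5/10), Indian (1/7) and
#' Others (6/5); slow-acetylator log-odds `beta_sa = log(10)` (reported
#' covariate-adjusted OR 9.98); female excess among cases
#' (`beta_female = log(4.9)`, the Table-1 cross-product OR); DILI grades
#' 2/3/4 among cases in proportions 10/24, 13/24, 1/24; tag-SNP/phenotype
#' concordance 0.981; and a rare-disease baseline `beta0 = -5` so that the
#' marginal enrichment of slow acetylators among cases matches the
#' reported cohort (about one third of patients slow).
#'
#' @param strata Tibble with columns `ethnicity`, `n_cases`, `n_controls`,
#'   `female_frac`.
#' @param haplotypes Haplotype table as from [nat2_haplotypes()]; either one
#'   table shared by all strata or a named list keyed by ethnicity.
#' @param tag_concordance Probability the tag-SNP genotype class matches the
#'   latent acetylator class.
#' @param tag_g_freq Population frequency of the tag-SNP G allele, used to
#'   split the non-AA classes into AG/GG.
#' @param n_background_snps Number of unlinked background SNPs.
#' @param background_divergence SD of the per-stratum logit-scale
#'   perturbation of background allele frequencies (an Fst-like divergence
#'   dial; drives PCA structure).
#' @param beta0,beta_sa,beta_female Logistic disease model: baseline
#'   log-odds, slow-acetylator log-OR, female log-OR.
#' @param grade_probs Named probabilities over DILI grades 2/3/4 among
#'   cases.
#' @param grade_trend Non-negative tilt; when positive, cases carrying more
#'   slow haplotypes are pushed towards higher grades (emulates a risk
#'   allele frequency rising with grade).
#' @param missing_rate Per-genotype missingness probability.
#' @param age_mean,age_sd Age distribution (years), truncated to 21-95.
#' @param seed Integer seed; all randomness in the generator flows from it.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(strata = default_strata(),
                       haplotypes = nat2_haplotypes(),
                       tag_concordance = 0.981,
                       tag_g_freq = 0.551,
                       n_background_snps = 200,
                       background_divergence = 0.15,
                       beta0 = -5,
                       beta_sa = log(10),
                       beta_female = log(4.9),
                       grade_probs = c(`2` = 10 / 24, `3` = 13 / 24, `4` = 1 / 24),
                       grade_trend = 0,
                       missing_rate = 0.005,
                       age_mean = 51.1,
                       age_sd = 14.5,
                       seed = 20171016) {
  strata <- as_tibble(strata)
  if (nrow(strata) == 0) abort("`strata` must have at least one row.")
  stopifnot(all(c("ethnicity", "n_cases", "n_controls", "female_frac") %in%
                names(strata)))
  if (any(strata$n_cases < 0 | strata$n_controls < 0)) {
    abort("Stratum sample sizes must be >= 0.")
  }
  assert_prob(strata$female_frac, "female_frac")
  assert_prob(tag_concordance, "tag_concordance")
  assert_prob(tag_g_freq, "tag_g_freq")
  assert_prob(missing_rate, "missing_rate")
  if (!is.list(haplotypes) || is.data.frame(haplotypes)) {
    haplotypes <- setNames(rep(list(as_tibble(haplotypes)), nrow(strata)),
                           strata$ethnicity)
  }
  if (!all(strata$ethnicity %in% names(haplotypes))) {
    abort("Every stratum needs a haplotype table.")
  }
  for (h in haplotypes) {
    if (abs(sum(h$freq) - 1) > 1e-9) {
      abort("Haplotype frequencies must sum to 1 (within 1e-9).")
    }
    if (any(h$freq < 0)) abort("Haplotype frequencies must be >= 0.")
  }
  if (abs(sum(grade_probs) - 1) > 1e-9 || any(grade_probs < 0)) {
    abort("`grade_probs` must be non-negative and sum to 1.")
  }
  if (is.null(names(grade_probs))) names(grade_probs) <- c("2", "3", "4")
  structure(list(
    strata = strata, haplotypes = haplotypes,
    tag_concordance = tag_concordance, tag_g_freq = tag_g_freq,
    n_background_snps = as.integer(n_background_snps),
    background_divergence = background_divergence,
    beta0 = beta0, beta_sa = beta_sa, beta_female = beta_female,
    grade_probs = grade_probs, grade_trend = grade_trend,
    missing_rate = missing_rate, age_mean = age_mean, age_sd = age_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default cohort strata
#'
#' Stratum sizes of the emulated cohort: 24 cases / 79 controls across the
#' four self-reported ethnicity groups, with the cohort-wide female
#' fraction (35/103) used in every stratum.
#' @return Tibble of strata.
#' @export
default_strata <- function() {
  tibble(
    ethnicity = c("Chinese", "Malay", "Indian", "Others"),
    n_cases = c(12L, 5L, 1L, 6L),
    n_controls = c(57L, 10L, 7L, 5L),
    female_frac = 35 / 103
  )
}

#' Default simulation configuration
#'
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config` emulating the reference study-scale cohort.
#' @export
default_sim_config <- function(...) sim_config(...)

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d strata, %d cases / %d controls, %d background SNPs, seed %d\n",
    nrow(x$strata), sum(x$strata$n_cases), sum(x$strata$n_controls),
    x$n_background_snps, x$seed))
  invisible(x)
}
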