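#' Run the full INH-DILI pharmacogenomic pipeline
#'
#' Orchestrates simulate -> qc -> acetylator calling -> association ->
#' clinical validity -> ROC comparison on a synthetic cohort (or on a
#' VCF + sample sheet you provide), writing one TSV per stage plus a YAML
#' manifest into `out_dir`.
#'
#' @param config A [sim_config()] used when simulating.
#' @param out_dir Output directory (created if needed).
#' @param vcf,sample_sheet Optional input paths; when given, the simulate
#'   stage is skipped and these are loaded instead.
#' @param seed Seed forwarded to every stochastic stage (overrides
#'   `config$seed` when given).
#' @param prevalence Assumed outcome prevalence for the validity stage.
#' @param prevalences Prevalence grid for the sensitivity sweep.
#' @param sample_call_rate,variant_call_rate,hwe_stratum,hwe_alpha,n_pcs
#'   QC thresholds (see [run_qc()]).
#' @param models Genetic models for the association stage.
#' @return Invisibly, a named list with each stage's results.
#' @export
run_dili_pipeline <- function(config = default_sim_config(),
                              out_dir = tempfile("dili_run_"),
                              vcf = NULL, sample_sheet = NULL,
                              seed = NULL,
                              prevalence = 0.10,
                              prevalences = seq(0.05, 0.20, by = 0.01),
                              sample_call_rate = 0.95,
                              variant_call_rate = 0.95,
                              hwe_stratum = "Chinese", hwe_alpha = 1e-6,
                              n_pcs = 10,
                              models = c("additive", "dominant",
                                         "recessive")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  t0 <- Sys.time()
  warnings_log <- character(0)
  note <- function(msg) warnings_log <<- c(warnings_log, msg)

  # --- inputs ---
  if (!is.null(vcf)) {
    if (is.null(sample_sheet)) abort("`sample_sheet` required with `vcf`.")
    if (!file.exists(vcf)) abort("Input VCF path does not exist.")
    geno <- read_genotype_vcf(vcf, panel = nat2_panel())
    samples <- read_sample_sheet(sample_sheet)
    cohort <- NULL
  } else {
    cohort <- generate_cohort(config, out_dir = out_dir)
    geno <- cohort$genotypes
    samples <- cohort$samples
  }

  # --- qc ---
  qc <- withCallingHandlers(
    run_qc(geno, samples, sample_call_rate, variant_call_rate,
           hwe_stratum, hwe_alpha, n_pcs = n_pcs),
    warning = function(w) {
      note(conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  samples <- qc$samples
  write.table(qc$report, file.path(out_dir, "qc_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(qc$pca$scores, file.path(out_dir, "pca_scores.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # --- acetylator calls ---
  calls <- infer_acetylator(qc$genotypes)
  tags <- classify_by_tag(qc$genotypes)
  conc <- tag_concordance(calls, tags)
  n_imputed <- sum(calls$imputed_snps != "")
  if (n_imputed) note(sprintf("%d samples had rs1801279 imputed to reference.",
                              n_imputed))
  calls_out <- calls %>%
    left_join(tags, by = "sample_id") %>%
    select("sample_id", "phenotype", "exposure", "imputed_snps",
           "tag_class", "refused_reason")
  write.table(calls_out, file.path(out_dir, "nat2_calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # --- association ---
  assoc <- withCallingHandlers(
    candidate_assoc(qc$genotypes, samples, models = models, pca = qc$pca,
                    n_pcs = min(2, n_pcs), adjust_seed = config$seed),
    warning = function(w) {
      note(conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  write.table(assoc, file.path(out_dir, "association.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # --- exposures for validity / roc ---
  sa <- calls[, c("sample_id", "exposure")]
  tag_aa <- tibble(sample_id = tags$sample_id,
                   exposure = tags$tag_class == "AA")
  tag_aa$exposure[tags$tag_class == "missing"] <- NA
  d1041983 <- dosage_of(qc$genotypes, "rs1041983")
  rec_1041983 <- tibble(sample_id = names(d1041983),
                        exposure = d1041983 == 2L)
  exposures <- list(SA = sa, rs1495741_AA = tag_aa,
                    rs1041983_AA = rec_1041983)
  sa_or <- logistic_assoc(
    samples$status,
    as.numeric(sa$exposure[match(samples$sample_id, sa$sample_id)]),
    covariates = data.frame(
      sex = as.integer(samples$sex == "F"),
      qc$pca$scores[match(samples$sample_id, qc$pca$scores$sample_id),
                    c("PC1", "PC2")]),
    label = "SA")
  validity <- purrr::imap_dfr(exposures, function(expo, lab) {
    tab <- exposure_table(expo, samples)
    or <- if (lab == "SA" && sa_or$estimable) sa_or$odds_ratio else NULL
    purrr::map_dfr(prevalences, function(pr)
      clinical_validity(tab, prevalence = pr, odds_ratio = or, label = lab))
  })
  write.table(validity, file.path(out_dir, "clinical_validity.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # --- grade trend ---
  grade_trend <- bind_rows(
    mutate(risk_allele_freq_by_grade(samples, exposure = sa), label = "SA"),
    mutate(risk_allele_freq_by_grade(samples, geno = qc$genotypes,
                                     variant = "rs1041983"),
           label = "rs1041983_A"),
    mutate(risk_allele_freq_by_grade(samples, geno = qc$genotypes,
                                     variant = "rs1495741",
                                     risk_is_counted = FALSE),
           label = "rs1495741_A")
  )
  write.table(grade_trend, file.path(out_dir, "grade_trend.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # --- roc ---
  roc_df <- samples %>%
    left_join(rename(sa, sa_status = "exposure"), by = "sample_id") %>%
    left_join(rename(tag_aa, tag_aa = "exposure"), by = "sample_id") %>%
    left_join(rename(rec_1041983, rs1041983_aa = "exposure"),
              by = "sample_id")
  roc <- withCallingHandlers(
    compare_risk_models(roc_df,
                        clinical = c("age", "sex", "ethnicity"),
                        genetic = c("sa_status", "tag_aa", "rs1041983_aa")),
    warning = function(w) {
      note(conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  write.table(roc$comparisons, file.path(out_dir, "roc_comparison.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # --- manifest ---
  manifest <- list(
    package = "nat2pgx",
    version = as.character(utils::packageVersion("nat2pgx")),
    seed = config$seed,
    config_hash = rlang::hash(config),
    n_samples_retained = nrow(samples),
    n_variants_retained = ncol(qc$genotypes$calls),
    tag_concordance = conc$concordance,
    assoc_family_size = attr(assoc, "family_size"),
    warnings = as.list(warnings_log),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(
    cohort = cohort, qc = qc, calls = calls, tags = tags,
    concordance = conc, association = assoc, validity = validity,
    grade_trend = grade_trend, roc = roc, manifest = manifest,
    out_dir = out_dir
  ))
}
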