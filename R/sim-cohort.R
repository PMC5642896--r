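#' @noRd
draw_latent <- function(config, n_by_stratum) {
  out <- purrr::map2_dfr(
    config$strata$ethnicity, n_by_stratum,
    function(eth, n) {
      if (n == 0) return(NULL)
      hap <- config$haplotypes[[eth]]
      i1 <- sample.int(nrow(hap), n, replace = TRUE, prob = hap$freq)
      i2 <- sample.int(nrow(hap), n, replace = TRUE, prob = hap$freq)
      n_slow <- as.integer(hap$slow[i1]) + as.integer(hap$slow[i2])
      fem_frac <- config$strata$female_frac[config$strata$ethnicity == eth]
      age <- pmin(95, pmax(21, round(rnorm(n, config$age_mean, config$age_sd))))
      tibble(
        ethnicity = eth, hap1 = i1, hap2 = i2, n_slow = n_slow,
        acet_class = c("RA", "IA", "SA")[n_slow + 1L],
        female = runif(n) < fem_frac,
        age = age
      )
    })
  out$acet_class <- factor(out$acet_class, levels = c("RA", "IA", "SA"))
  out
}

#' @noRd
expected_case_rate <- function(config, eth) {
  hap <- config$haplotypes[[eth]]
  q_slow <- sum(hap$freq[hap$slow])
  p_sa <- q_slow^2
  fem <- config$strata$female_frac[config$strata$ethnicity == eth]
  cells <- expand.grid(sa = c(0, 1), female = c(0, 1))
  w <- ifelse(cells$sa == 1, p_sa, 1 - p_sa) *
    ifelse(cells$female == 1, fem, 1 - fem)
  p <- stats::plogis(config$beta0 + config$beta_sa * cells$sa +
                       config$beta_female * cells$female)
  sum(w * p)
}

#' Assign case-control phenotypes to a latent pool
#'
#' Applies the retrospective disease model to a latent pool of individuals:
#' case status is Bernoulli with
#' `logit(p) = beta0 + beta_sa * [SA] + beta_female * [female]`, then
#' exactly `n_cases` cases and `n_controls` controls per stratum are sampled
#' from the realized groups (re-drawing statuses if a stratum's quota is not
#' reachable from the pool, up to `max_tries`). Selected cases receive a
#' DILI grade from `grade_probs` (tilted towards higher grades for slow
#' haplotype carriers when `grade_trend > 0`); controls receive grade 0.
#'
#' @param truth Latent pool tibble as produced by the generator (columns
#'   `ethnicity`, `n_slow`, `acet_class`, `female`, `age`).
#' @param config A [sim_config()].
#' @param select Enforce the configured per-stratum case/control counts
#'   exactly (the case-control design); when `FALSE` the Bernoulli statuses
#'   are returned for the whole pool.
#' @param max_tries Status re-draw attempts before giving up.
#' @param seed Seed for this call when used standalone; `NULL` (the
#'   default) draws from the current RNG stream, which is how
#'   [generate_cohort()] calls it.
#' @return The selected (or full) pool with `status`, `grade` columns.
#' @export
assign_phenotypes <- function(truth, config, select = TRUE,
                              max_tries = 25, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, assign_phenotypes(truth, config,
                                                    select, max_tries)))
  }
  lp <- config$beta0 + config$beta_sa * (truth$acet_class == "SA") +
    config$beta_female * truth$female
  if (!select) {
    truth$status <- ifelse(runif(nrow(truth)) < stats::plogis(lp),
                           "case", "control")
    truth$grade <- ifelse(truth$status == "case",
                          draw_grades(truth$n_slow, config), 0L)
    return(truth)
  }
  p <- stats::plogis(lp)
  picked <- NULL
  for (try in seq_len(max_tries)) {
    status <- ifelse(runif(nrow(truth)) < p, "case", "control")
    ok <- TRUE
    sel_idx <- integer(0)
    for (s in seq_len(nrow(config$strata))) {
      eth <- config$strata$ethnicity[s]
      in_s <- which(truth$ethnicity == eth)
      ca <- in_s[status[in_s] == "case"]
      co <- in_s[status[in_s] == "control"]
      if (length(ca) < config$strata$n_cases[s] ||
          length(co) < config$strata$n_controls[s]) {
        ok <- FALSE
        break
      }
      sel_idx <- c(sel_idx,
                   sample_keep(ca, config$strata$n_cases[s]),
                   sample_keep(co, config$strata$n_controls[s]))
    }
    if (ok) {
      picked <- sel_idx
      break
    }
  }
  if (is.null(picked)) {
    abort("Requested case/control counts unreachable from this pool.")
  }
  out <- truth[picked, ]
  out$status <- status[picked]
  out$grade <- 0L
  is_case <- out$status == "case"
  out$grade[is_case] <- draw_grades(out$n_slow[is_case], config)
  out
}

# sample() with the size-1 gotcha avoided
sample_keep <- function(x, k) {
  if (length(x) == k) return(x)
  x[sample.int(length(x), k)]
}

#' @noRd
draw_grades <- function(n_slow, config) {
  grades <- as.integer(names(config$grade_probs))
  vapply(n_slow, function(ns) {
    w <- config$grade_probs * exp(config$grade_trend * seq_along(grades) * ns)
    grades[sample.int(length(grades), 1, prob = w / sum(w))]
  }, integer(1))
}

#' @noRd
materialize_genotypes <- function(truth, config) {
  snps <- nat2_snps()
  n <- nrow(truth)
  sample_ids <- truth$sample_id
  # NAT2 coding SNP dosages from the two haplotypes
  nat2 <- matrix(0L, n, length(snps), dimnames = list(sample_ids, snps))
  for (s in seq_len(nrow(config$strata))) {
    eth <- config$strata$ethnicity[s]
    rows <- which(truth$ethnicity == eth)
    if (!length(rows)) next
    hm <- as.matrix(config$haplotypes[[eth]][, snps])
    nat2[rows, ] <- hm[truth$hap1[rows], , drop = FALSE] +
      hm[truth$hap2[rows], , drop = FALSE]
  }
  # tag SNP: dosage counts G; class AA (dosage 0) is concordant with SA
  g <- config$tag_g_freq
  p_non_aa <- c(2 * g * (1 - g), g^2) # AG, GG
  draw_non_aa <- function(k) {
    sample(c(1L, 2L), k, replace = TRUE, prob = p_non_aa / sum(p_non_aa))
  }
  sa <- truth$acet_class == "SA"
  concord <- runif(n) < config$tag_concordance
  tag <- integer(n)
  tag[sa & concord] <- 0L
  tag[!sa & !concord] <- 0L
  k <- sum(sa != concord) # non-AA draws: concordant non-SA or discordant SA
  tag[sa != concord] <- draw_non_aa(k)
  # background SNPs in per-stratum Hardy-Weinberg proportions
  nbg <- config$n_background_snps
  bg <- NULL
  bg_freqs <- NULL
  if (nbg > 0) {
    base_maf <- runif(nbg, 0.05, 0.5)
    bg_freqs <- vapply(seq_len(nrow(config$strata)), function(s) {
      stats::plogis(stats::qlogis(base_maf) +
                      rnorm(nbg, 0, config$background_divergence))
    }, numeric(nbg))
    colnames(bg_freqs) <- config$strata$ethnicity
    bg <- matrix(0L, n, nbg,
                 dimnames = list(sample_ids,
                                 sprintf("bg%04d", seq_len(nbg))))
    for (s in seq_len(nrow(config$strata))) {
      rows <- which(truth$ethnicity == config$strata$ethnicity[s])
      if (!length(rows)) next
      bg[rows, ] <- t(vapply(rows, function(i)
        rbinom(nbg, 2L, bg_freqs[, s]), integer(nbg)))
    }
  }
  calls <- cbind(nat2, rs1495741 = tag, bg)
  if (config$missing_rate > 0) {
    calls[runif(length(calls)) < config$missing_rate] <- NA_integer_
  }
  nat2_vars <- nat2_variant_table()
  variants <- nat2_vars[match(c(snps, "rs1495741"), nat2_vars$id), ]
  if (nbg > 0) {
    variants <- bind_rows(variants, tibble(
      id = colnames(bg),
      chrom = as.character(rep_len(1:22, nbg)),
      pos = 1000000L + 1000L * seq_len(nbg),
      counted_allele = "G", other_allele = "A", gene = NA_character_
    ))
  }
  list(genotypes = geno_matrix(calls[, variants$id, drop = FALSE], variants),
       bg_freqs = bg_freqs)
}

#' Simulate genotypes for a cohort-sized draw
#'
#' Draws each sample's two NAT2 haplotypes from its stratum's haplotype
#' distribution, sets the rs1495741 tag genotype to the class concordant
#' with the latent acetylator phenotype with probability
#' `tag_concordance` (else a discordant class), draws unlinked background
#' SNPs in per-stratum Hardy-Weinberg proportions, and applies independent
#' missingness. Deterministic for a fixed seed.
#'
#' @param config A [sim_config()].
#' @param n_by_stratum Optional integer vector of draws per stratum;
#'   defaults to `n_cases + n_controls` per stratum.
#' @param seed Seed; defaults to `config$seed`. Use `NULL` to draw from the
#'   current RNG stream.
#' @return List with `genotypes` (a [geno_matrix()]) and `truth` (latent
#'   per-sample tibble plus per-stratum background allele frequencies).
#' @export
simulate_genotypes <- function(config, n_by_stratum = NULL,
                               seed = config$seed) {
  run <- function() {
    n_by <- n_by_stratum %||%
      (config$strata$n_cases + config$strata$n_controls)
    truth <- draw_latent(config, n_by)
    truth$sample_id <- sprintf("S%04d", seq_len(nrow(truth)))
    mat <- materialize_genotypes(truth, config)
    list(genotypes = mat$genotypes,
         truth = list(latent = truth, bg_freqs = mat$bg_freqs))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a complete synthetic case-control cohort
#'
#' Composes the latent haplotype draw, the retrospective disease model with
#' exact per-stratum case/control counts, and genotype materialization into
#' one seeded, reproducible cohort. A latent population pool is grown per
#' stratum until the configured quotas are reachable, mirroring
#' retrospective case-control ascertainment from a larger source
#' population.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, a VCF
#'   (`genotypes.vcf`) and sample sheet (`samples.tsv`) are written there.
#' @return A `sim_cohort` list: `genotypes` ([geno_matrix()]), `samples`
#'   (sample sheet tibble), `truth` (latent classes, haplotypes and
#'   per-stratum background allele frequencies).
#' @examples
#' cohort <- generate_cohort(sim_config(n_background_snps = 20, seed = 1))
#' dplyr::count(cohort$samples, status)
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  out <- withr::with_seed(config$seed, {
    rate <- vapply(config$strata$ethnicity,
                   function(e) expected_case_rate(config, e), numeric(1))
    need_cases <- config$strata$n_cases
    need_ctrls <- config$strata$n_controls
    pool_n <- pmax(200L, need_cases + need_ctrls + 50L,
                   ceiling(3 * need_cases / pmax(rate, 1e-4)))
    pool_n <- pmin(pool_n, 20000L)
    selected <- NULL
    for (attempt in 1:6) {
      pool <- draw_latent(config, pool_n)
      selected <- tryCatch(
        assign_phenotypes(pool, config, select = TRUE),
        error = function(e) NULL)
      if (!is.null(selected)) break
      pool_n <- pool_n * 2L
    }
    if (is.null(selected)) {
      abort("Requested case/control counts unreachable under this disease model.")
    }
    selected <- selected %>%
      mutate(.ord = match(.data$ethnicity, config$strata$ethnicity)) %>%
      arrange(.data$.ord, .data$status != "case") %>%
      select(-".ord")
    selected$sample_id <- sprintf("S%04d", seq_len(nrow(selected)))
    mat <- materialize_genotypes(selected, config)
    samples <- selected %>%
      mutate(sex = ifelse(.data$female, "F", "M")) %>%
      select("sample_id", "sex", "ethnicity", "status", "grade", "age")
    truth <- list(
      latent = selected %>%
        select("sample_id", "ethnicity", "hap1", "hap2", "n_slow",
               "acet_class", "female", "status", "grade"),
      bg_freqs = mat$bg_freqs,
      haplotypes = config$haplotypes
    )
    list(genotypes = mat$genotypes, samples = samples, truth = truth)
  })
  out <- structure(out, class = "sim_cohort")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_genotype_vcf(out$genotypes, file.path(out_dir, "genotypes.vcf"))
    write_sample_sheet(out$samples, file.path(out_dir, "samples.tsv"))
  }
  out
}

#' @export
print.sim_cohort <- function(x, ...) {
  n <- table(x$samples$status)
  cat(sprintf("<sim_cohort> %d cases / %d controls, %d variants\n",
              n[["case"]], n[["control"]], ncol(x$genotypes$calls)))
  invisible(x)
}
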