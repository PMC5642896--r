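#' Code a dosage vector under a genetic model
#'
#' Additive keeps the 0/1/2 dosage; dominant codes carriers (dosage >= 1)
#' as 1; recessive codes homozygous variant (dosage 2) as 1. Missing
#' dosages propagate as `NA`.
#'
#' @param dosage Integer vector of counted-allele dosages.
#' @param model `"additive"`, `"dominant"` or `"recessive"`.
#' @return Numeric coded vector.
#' @export
code_genetic_model <- function(dosage,
                               model = c("additive", "dominant", "recessive")) {
  model <- match.arg(model)
  switch(model,
         additive = as.numeric(dosage),
         dominant = as.numeric(dosage >= 1),
         recessive = as.numeric(dosage == 2))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by the point-probability convention: with both
#' margins fixed, sum the hypergeometric probabilities of every table whose
#' probability does not exceed that of the observed table. The reported
#' odds ratio is the sample cross-product `(a*d)/(b*c)` (not the
#' conditional MLE), flagged infinite/zero on empty off-cells.
#'
#' @param a,b,c,d Counts: exposed cases, exposed controls, unexposed cases,
#'   unexposed controls.
#' @return One-row tibble (`p_value`, `odds_ratio`, `degenerate`).
#' @examples
#' fisher_exact_2x2(9, 59, 15, 20) # male gender vs case status
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Counts must be non-negative integers.")
  }
  m1 <- a + b  # exposed margin
  n1 <- a + c  # case margin
  tot <- a + b + c + d
  if (m1 == 0 || m1 == tot || n1 == 0 || n1 == tot) {
    or <- (a * d) / (b * c)
    return(tibble(p_value = 1, odds_ratio = or, degenerate = TRUE))
  }
  support <- max(0, n1 + m1 - tot):min(m1, n1)
  probs <- dhyper(support, m1, tot - m1, n1)
  obs <- probs[match(a, support)]
  p <- min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
  or <- (a * d) / (b * c)
  tibble(p_value = p, odds_ratio = or,
         degenerate = !is.finite(or) || or == 0)
}

#' Logistic regression association for one coded predictor
#'
#' Maximum-likelihood logistic fit of case status on a model-coded genotype
#' (or any exposure) with optional covariates, reporting the Wald 95% CI
#' and two-sided p for the predictor. The result is flagged inestimable
#' when the coded predictor is constant within cases or within controls,
#' or when the fit separates (divergent coefficient), mirroring how such
#' SNP-model combinations are reported as NA in small cohorts.
#'
#' @param status Character/factor vector, `"case"`/`"control"` (or logical
#'   case indicator).
#' @param predictor Numeric coded predictor (missing values allowed;
#'   complete-case analysis).
#' @param covariates Optional data frame of covariates (e.g. sex and the
#'   first 2 PCs).
#' @param label,model Labels carried into the result row.
#' @return One-row tibble (`snp`, `model`, `n`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `estimable`, `reason`).
#' @export
logistic_assoc <- function(status, predictor, covariates = NULL,
                           label = "exposure", model = "binary") {
  y <- if (is.logical(status)) status else status == "case"
  df <- data.frame(y = y, x = predictor)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  base <- tibble(snp = label, model = model, n = nrow(df),
                 odds_ratio = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, p_value = NA_real_,
                 estimable = FALSE, reason = NA_character_)
  if (!nrow(df) || all(is.na(df$x))) {
    base$reason <- "no_data"
    return(base)
  }
  if (sum(df$y) == 0 || sum(!df$y) == 0) {
    base$reason <- "single_class"
    return(base)
  }
  if (var(df$x) == 0) {
    base$reason <- "predictor_constant"
    return(base)
  }
  if (var(df$x[df$y]) == 0 || var(df$x[!df$y]) == 0) {
    base$reason <- "constant_within_group"
    return(base)
  }
  fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
  co <- summary(fit)$coefficients
  if (!"x" %in% rownames(co)) {
    base$reason <- "not_estimable"
    return(base)
  }
  beta <- co["x", "Estimate"]
  se <- co["x", "Std. Error"]
  if (!is.finite(beta) || abs(beta) > 15 || !is.finite(se) || se > 100) {
    base$reason <- "separation"
    return(base)
  }
  base %>% mutate(
    odds_ratio = exp(beta),
    ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se),
    p_value = 2 * pnorm(-abs(beta / se)),
    estimable = TRUE, reason = NA_character_
  )
}

#' Adjust correlated association p-values via multivariate normal
#' probabilities
#'
#' Adjusts a family of two-sided p-values for multiple correlated tests:
#' the correlation matrix of the test statistics is estimated as the
#' pairwise correlation of the covariate-residualized coded predictor
#' vectors (the score-test approximation), and each adjusted p is
#' `1 - Pr(|Z_j| <= z_i for all j)` under the zero-mean multivariate
#' normal with that correlation, computed by quasi-random integration to
#' absolute tolerance 1e-4. Adjusted values are clipped to `[raw, 1]`.
#'
#' @param p Raw two-sided p-values of the estimable tests.
#' @param predictors Matrix/data frame, one column per test, of the coded
#'   predictor vectors (aligned samples; `NA` allowed).
#' @param covariates Optional covariate data frame to residualize on.
#' @param seed Seed for the quasi-random integration.
#' @return Numeric vector of adjusted p-values.
#' @export
p_act_adjust <- function(p, predictors, covariates = NULL, seed = 1L) {
  predictors <- as.matrix(predictors)
  m <- ncol(predictors)
  if (length(p) != m) abort("One predictor column per p-value required.")
  if (m == 1) return(pmin(1, p))
  res <- predictors
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)
    for (j in seq_len(m)) {
      ok <- !is.na(predictors[, j]) & stats::complete.cases(cv)
      r <- rep(NA_real_, nrow(predictors))
      r[ok] <- residuals(lm(predictors[ok, j] ~ ., data = cv[ok, , drop = FALSE]))
      res[, j] <- r
    }
  }
  cm <- suppressWarnings(cor(res, use = "pairwise.complete.obs"))
  cm[is.na(cm)] <- 0
  diag(cm) <- 1
  ev <- eigen(cm, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    warn("Correlation estimate repaired to positive semidefinite by eigenvalue clipping.")
    lam <- pmax(ev$values, 1e-8)
    cm <- ev$vectors %*% diag(lam) %*% t(ev$vectors)
    cm <- stats::cov2cor(cm)
  }
  withr::with_seed(seed, {
    vapply(seq_along(p), function(i) {
      z <- qnorm(1 - p[i] / 2)
      if (!is.finite(z)) return(p[i])
      pr <- mvtnorm::pmvnorm(lower = rep(-z, m), upper = rep(z, m),
                             corr = cm,
                             algorithm = mvtnorm::GenzBretz(abseps = 1e-4,
                                                            maxpts = 100000))
      min(1, max(p[i], 1 - as.numeric(pr)))
    }, numeric(1))
  })
}

#' Candidate-SNP association across genetic models
#'
#' Runs [logistic_assoc()] for every panel SNP under each requested genetic
#' model, with sex and the first `n_pcs` principal components as
#' covariates, then adjusts the estimable family for multiple correlated
#' tests with [p_act_adjust()]. The family size is whatever is estimable
#' at runtime and is recorded in the `family_size` attribute.
#'
#' @param geno A [geno_matrix()].
#' @param samples Sample sheet with `sample_id`, `sex`, `status`.
#' @param panel Tibble with a column `id` of SNP ids to test (defaults to
#'   every NAT2 SNP plus the tag SNP in the matrix).
#' @param models Genetic models to test.
#' @param pca Optional [genotype_pca()] result supplying PC covariates.
#' @param n_pcs Number of PCs used as covariates.
#' @param adjust_seed Seed for the adjustment integration.
#' @return Tibble, one row per SNP x model, with `p_adjusted` added.
#' @export
candidate_assoc <- function(geno, samples, panel = NULL,
                            models = c("additive", "dominant", "recessive"),
                            pca = NULL, n_pcs = 2, adjust_seed = 1L) {
  if (is.null(panel)) {
    ids <- geno$variants$id[!is.na(geno$variants$gene)]
    panel <- tibble(id = ids)
  }
  ord <- match(samples$sample_id, rownames(geno$calls))
  if (anyNA(ord)) abort("Every sample needs genotypes.")
  cov <- data.frame(sex = as.integer(samples$sex == "F"))
  if (!is.null(pca) && n_pcs > 0) {
    sc <- pca$scores[match(samples$sample_id, pca$scores$sample_id), ]
    cov <- cbind(cov, as.data.frame(sc[, paste0("PC", seq_len(n_pcs))]))
  }
  rows <- list()
  preds <- list()
  for (id in panel$id) {
    dos <- geno$calls[ord, id]
    for (mdl in models) {
      coded <- code_genetic_model(dos, mdl)
      key <- paste(id, mdl, sep = ".")
      preds[[key]] <- coded
      rows[[key]] <- logistic_assoc(samples$status, coded, cov,
                                    label = id, model = mdl)
    }
  }
  out <- bind_rows(rows)
  est <- which(out$estimable)
  out$p_adjusted <- NA_real_
  if (length(est)) {
    pm <- do.call(cbind, preds[est])
    out$p_adjusted[est] <- p_act_adjust(out$p_value[est], pm, cov,
                                        seed = adjust_seed)
  }
  attr(out, "family_size") <- length(est)
  out
}

#' Association within ethnicity strata
#'
#' Re-runs an exposure association separately in each ethnicity stratum
#' (without PC covariates, which are meaningless within a stratum).
#'
#' @param samples Sample sheet tibble.
#' @param exposure Tibble (`sample_id`, `exposure`) - e.g. SA status - or a
#'   [geno_matrix()] plus `variant`/`model` to code.
#' @param geno,variant,model Optional genotype-based exposure definition.
#' @param strata Ethnicity labels to analyse (default: all present).
#' @return Tibble, one row per stratum.
#' @export
subgroup_assoc <- function(samples, exposure = NULL, geno = NULL,
                           variant = NULL, model = "additive",
                           strata = NULL) {
  if (is.null(exposure)) {
    dos <- dosage_of(geno, variant)
    exposure <- tibble(sample_id = names(dos),
                       exposure = code_genetic_model(dos, model))
  }
  df <- left_join(samples, exposure, by = "sample_id")
  purrr::map_dfr(strata %||% unique(df$ethnicity), function(eth) {
    sub <- df[df$ethnicity == eth, ]
    if (!nrow(sub)) abort(sprintf("Empty stratum %s.", eth))
    res <- logistic_assoc(sub$status, as.numeric(sub$exposure),
                          covariates = data.frame(
                            sex = as.integer(sub$sex == "F")),
                          label = variant %||% "exposure", model = model)
    mutate(res, ethnicity = eth, .before = 1)
  })
}

#' Clinical covariate comparisons between cases and controls
#'
#' Compares baseline variables between cases and controls with the
#' conventional test for each variable type: t-test for normal continuous
#' variables, Mann-Whitney U for skewed continuous variables, Yates
#' chi-square for standalone binary variables when all expected cell
#' counts are at least 5 (Fisher's exact otherwise), and Fisher's exact
#' test for each level of a multi-level categorical variable against all
#' other levels combined (plus an overall Fisher test across levels). All
#' tests are two-sided.
#'
#' @param samples Sample sheet tibble with a `status` column.
#' @param variables Tibble (`variable`, `type`) where `type` is one of
#'   `continuous_normal`, `continuous_skewed`, `binary`, `categorical`.
#'   A `binary` variable column must be logical (or 0/1).
#' @return Tibble (`variable`, `level`, `test`, `p_value`, `flag`).
#' @export
clinical_covariate_tests <- function(samples, variables) {
  y <- samples$status == "case"
  purrr::pmap_dfr(variables, function(variable, type) {
    x <- samples[[variable]]
    if (length(unique(na.omit(x))) < 2) {
      return(tibble(variable = variable, level = NA_character_,
                    test = "none", p_value = 1, flag = "constant"))
    }
    if (type == "continuous_normal") {
      p <- t.test(x ~ y)$p.value
      return(tibble(variable = variable, level = NA_character_,
                    test = "t", p_value = p, flag = NA_character_))
    }
    if (type == "continuous_skewed") {
      p <- suppressWarnings(wilcox.test(x ~ y)$p.value)
      return(tibble(variable = variable, level = NA_character_,
                    test = "mann_whitney", p_value = p, flag = NA_character_))
    }
    if (type == "binary") {
      tab <- table(factor(as.logical(x), levels = c(TRUE, FALSE)),
                   factor(y, levels = c(TRUE, FALSE)))
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (all(expected >= 5)) {
        p <- suppressWarnings(chisq.test(tab)$p.value)
        test <- "chi_square"
      } else {
        p <- fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1],
                              tab[2, 2])$p_value
        test <- "fisher"
      }
      return(tibble(variable = variable, level = NA_character_,
                    test = test, p_value = p, flag = NA_character_))
    }
    # categorical: overall r x 2 Fisher plus each level vs rest
    lv <- sort(unique(as.character(x)))
    overall <- fisher.test(table(x, y))$p.value
    rows <- purrr::map_dfr(lv, function(l) {
      in_l <- as.character(x) == l
      tibble(variable = variable, level = l, test = "fisher",
             p_value = fisher_exact_2x2(sum(in_l & y), sum(in_l & !y),
                                        sum(!in_l & y),
                                        sum(!in_l & !y))$p_value,
             flag = NA_character_)
    })
    bind_rows(tibble(variable = variable, level = "(overall)",
                     test = "fisher_rxc", p_value = overall,
                     flag = NA_character_), rows)
  })
}

#' Simulation-based power for an allelic case-control test
#'
#' Simulates case/control minor-allele counts at the design's allele
#' numbers, with the case allele frequency implied by the allelic odds
#' ratio, tests each replicate's allelic 2x2 table with Fisher's exact
#' test at level `alpha`, and reports the rejection fraction with its
#' Monte Carlo standard error.
#'
#' @param n_cases,n_controls Sample sizes (individuals; alleles are 2n).
#' @param maf Control-group minor-allele frequency.
#' @param odds_ratio Allelic odds ratio under the alternative.
#' @param alpha Significance level.
#' @param n_reps Replicates (>= 100).
#' @param seed Seed.
#' @return One-row tibble (`power`, `se`, `n_reps`).
#' @examples
#' power_simulation(24, 79, maf = 0.3, odds_ratio = 50, n_reps = 200)
#' @export
power_simulation <- function(n_cases, n_controls, maf, odds_ratio,
                             alpha = 0.003, n_reps = 2000, seed = 1L) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  if (n_reps < 100) abort("Use at least 100 replicates.")
  if (maf <= 0 || maf >= 1) abort("Degenerate allele frequency.")
  p1 <- maf * odds_ratio / (1 + maf * (odds_ratio - 1))
  a_case <- 2L * n_cases
  a_ctrl <- 2L * n_controls
  rej <- withr::with_seed(seed, {
    ka <- rbinom(n_reps, a_case, p1)
    kc <- rbinom(n_reps, a_ctrl, maf)
    vapply(seq_len(n_reps), function(i) {
      fisher_exact_2x2(ka[i], kc[i], a_case - ka[i],
                       a_ctrl - kc[i])$p_value < alpha
    }, logical(1))
  })
  pw <- mean(rej)
  tibble(power = pw, se = sqrt(pw * (1 - pw) / n_reps), n_reps = n_reps)
}
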