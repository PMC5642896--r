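test_that("genetic model coding follows the standard definitions", {
  d <- c(0L, 1L, 2L, NA)
  expect_equal(code_genetic_model(d, "additive"), c(0, 1, 2, NA))
  expect_equal(code_genetic_model(d, "dominant"), c(0, 1, 1, NA))
  expect_equal(code_genetic_model(d, "recessive"), c(0, 0, 1, NA))
})

test_that("Fisher 2x2 reproduces enumerable and published p-values", {
  expect_equal(fisher_exact_2x2(2, 0, 0, 2)$p_value, 1 / 3,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(5, 5, 5, 5)$p_value, 1)
  # ethnicity comparisons from the emulated cohort's baseline table
  expect_equal(signif(fisher_exact_2x2(6, 5, 18, 74)$p_value, 2), 0.018)
  expect_equal(signif(fisher_exact_2x2(12, 57, 12, 22)$p_value, 2), 0.051)
  # degenerate margin
  deg <- fisher_exact_2x2(0, 0, 3, 4)
  expect_equal(deg$p_value, 1)
  expect_true(deg$degenerate)
  # random tables agree with stats::fisher.test (same convention)
  set.seed(2)
  for (i in 1:40) {
    t <- rmultinom(1, sample(10:60, 1), rep(0.25, 4))
    expect_equal(
      fisher_exact_2x2(t[1], t[2], t[3], t[4])$p_value,
      stats::fisher.test(matrix(t, 2))$p.value, tolerance = 1e-9)
  }
})

test_that("odds ratios are invariant to jointly swapping labels and exposure", {
  res <- fisher_exact_2x2(9, 59, 15, 20)
  swapped <- fisher_exact_2x2(20, 15, 59, 9) # unexposed-control first
  expect_equal(res$odds_ratio, swapped$odds_ratio)
  expect_equal(res$p_value, swapped$p_value)
})

test_that("covariate-free logistic association equals the cross-product OR", {
  y <- rep(c(TRUE, FALSE), c(40, 60))
  x <- c(rep(1, 25), rep(0, 15), rep(1, 20), rep(0, 40))
  res <- logistic_assoc(y, x)
  or_2x2 <- (25 * 40) / (20 * 15)
  expect_equal(res$odds_ratio, or_2x2, tolerance = 1e-3)
  expect_true(res$estimable)
  expect_true(res$ci_low <= res$odds_ratio && res$odds_ratio <= res$ci_high)
})

test_that("inestimable genotype configurations are flagged, not fitted", {
  y <- rep(c(TRUE, FALSE), c(10, 30))
  # no homozygous-variant carriers at all: recessive coding constant
  x <- code_genetic_model(rep(c(0L, 1L), 20), "recessive")
  res <- logistic_assoc(y, x)
  expect_false(res$estimable)
  expect_equal(res$reason, "predictor_constant")
  expect_true(is.na(res$odds_ratio))
  # carriers only among cases: constant within a group
  x2 <- c(rep(1, 10), rep(0, 30))
  res2 <- logistic_assoc(y, x2)
  expect_false(res2$estimable)
  expect_equal(res2$reason, "constant_within_group")
})

test_that("logistic association holds its nominal type-I error", {
  set.seed(33)
  rej <- vapply(1:500, function(i) {
    y <- rep(c(TRUE, FALSE), c(24, 79))
    x <- rbinom(103, 2, 0.3)
    res <- logistic_assoc(y, x)
    isTRUE(res$p_value < 0.05)
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("correlated-test adjustment respects its analytic limits", {
  # single test: unchanged
  expect_equal(p_act_adjust(0.05, matrix(rnorm(50))), 0.05)
  set.seed(44)
  # duplicated tests: perfect correlation collapses the adjustment
  x <- rnorm(300)
  expect_warning(adj <- p_act_adjust(c(0.03, 0.03), cbind(x, x)),
                 "positive semidefinite")
  expect_equal(adj, c(0.03, 0.03), tolerance = 2e-3)
  # independent tests: Sidak closed form
  pm <- matrix(rnorm(2000 * 10), 2000, 10)
  adj10 <- p_act_adjust(rep(0.01, 10), pm)
  expect_equal(adj10, rep(1 - (1 - 0.01)^10, 10), tolerance = 2e-3)
})

test_that("adjusted p-values are bounded by raw p and the Sidak bound", {
  set.seed(45)
  for (rep in 1:5) {
    m <- sample(3:8, 1)
    n <- 150
    base <- rnorm(n)
    pm <- vapply(1:m, function(j) 0.6 * base + rnorm(n), numeric(n))
    p <- runif(m, 0.001, 0.5)
    adj <- p_act_adjust(p, pm)
    expect_true(all(adj >= p - 1e-3))
    expect_true(all(adj <= pmin(1, 1 - (1 - p)^m) + 2e-3))
    expect_true(all(adj <= 1))
  }
})

test_that("candidate association mirrors the cohort's expected pattern", {
  co <- generate_cohort(sim_config(seed = 42))
  qc <- run_qc(co$genotypes, co$samples)
  res <- suppressWarnings(
    candidate_assoc(qc$genotypes, qc$samples, pca = qc$pca))
  expect_true(all(res$p_adjusted >= res$p_value - 1e-9, na.rm = TRUE))
  expect_true(all(res$ci_low <= res$odds_ratio & res$odds_ratio <= res$ci_high,
                  na.rm = TRUE))
  expect_true(all(is.na(res$odds_ratio[!res$estimable])))
  expect_true(all(!is.na(res$reason[!res$estimable])))
  expect_equal(attr(res, "family_size"), sum(res$estimable))
  # the protective tag SNP comes out with OR < 1 under the dominant model
  tag_dom <- res[res$snp == "rs1495741" & res$model == "dominant", ]
  expect_lt(tag_dom$odds_ratio, 1)
})

test_that("single-stratum subgroup analysis equals the unstratified fit", {
  co <- generate_cohort(sim_config(
    strata = tibble::tibble(ethnicity = "Chinese", n_cases = 20L,
                            n_controls = 60L, female_frac = 0.4),
    n_background_snps = 0, missing_rate = 0, seed = 50))
  calls <- infer_acetylator(co$genotypes)
  expo <- calls[, c("sample_id", "exposure")]
  sub <- subgroup_assoc(co$samples, exposure = expo)
  whole <- logistic_assoc(
    co$samples$status,
    as.numeric(expo$exposure[match(co$samples$sample_id, expo$sample_id)]),
    covariates = data.frame(sex = as.integer(co$samples$sex == "F")))
  expect_equal(sub$odds_ratio, whole$odds_ratio, tolerance = 1e-9)
  expect_equal(sub$p_value, whole$p_value, tolerance = 1e-9)
  # a requested stratum with no samples errors
  expect_error(subgroup_assoc(co$samples, exposure = expo,
                              strata = "Martian"), "Empty stratum")
})

test_that("clinical covariate tests reproduce the baseline-table values", {
  sheet <- sheet_from_counts(
    a = list(status = "case", sex = "F", n = 15),
    b = list(status = "case", sex = "M", n = 9),
    c = list(status = "control", sex = "F", n = 20),
    d = list(status = "control", sex = "M", n = 59))
  sheet$ethnicity[sheet$status == "case"] <-
    rep(c("Chinese", "Malay", "Indian", "Others"), c(12, 5, 1, 6))
  sheet$ethnicity[sheet$status == "control"] <-
    rep(c("Chinese", "Malay", "Indian", "Others"), c(57, 10, 7, 5))
  sheet$male <- sheet$sex == "M"
  res <- clinical_covariate_tests(
    sheet, tibble::tibble(variable = c("male", "ethnicity"),
                          type = c("binary", "categorical")))
  male_p <- res$p_value[res$variable == "male"]
  expect_equal(signif(male_p, 3), 1.80e-3)
  expect_equal(res$test[res$variable == "male"], "chi_square")
  expect_equal(signif(res$p_value[res$level %in% "Others"], 2), 0.018)
  expect_equal(signif(res$p_value[res$level %in% "Chinese"], 2), 0.051)
  # constant variable: flagged with p = 1
  sheet$const <- 1
  res2 <- clinical_covariate_tests(
    sheet, tibble::tibble(variable = "const", type = "binary"))
  expect_equal(res2$p_value, 1)
  expect_equal(res2$flag, "constant")
})

test_that("Mann-Whitney comparison holds its nominal level under the null", {
  set.seed(55)
  rej <- vapply(1:400, function(i) {
    sheet <- tibble::tibble(
      status = rep(c("case", "control"), c(24, 79)),
      lft = rexp(103, 1))
    res <- clinical_covariate_tests(
      sheet, tibble::tibble(variable = "lft", type = "continuous_skewed"))
    res$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.08)
})

test_that("power simulation is calibrated at the null and saturates", {
  null <- power_simulation(24, 79, maf = 0.3, odds_ratio = 1,
                           alpha = 0.05, n_reps = 400, seed = 60)
  expect_lte(null$power, 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
  extreme <- power_simulation(24, 79, maf = 0.3, odds_ratio = 50,
                              alpha = 0.003, n_reps = 300, seed = 61)
  expect_gt(extreme$power, 0.99)
  expect_error(power_simulation(24, 79, maf = 0, odds_ratio = 2),
               "Degenerate")
  expect_error(power_simulation(24, 79, 0.3, 2, alpha = 1.5), "alpha")
})
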