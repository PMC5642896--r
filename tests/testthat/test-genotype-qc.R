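test_that("call-rate filter removes exactly the low-call-rate rows/columns", {
  set.seed(4)
  m <- matrix(sample(0:2, 40 * 60, replace = TRUE), 40, 60)
  g <- make_geno(m)
  res <- call_rate_filter(g, 0.95, 0.95)
  expect_equal(nrow(res$removed), 0)

  m2 <- m
  m2[1, 1:6] <- NA # sample 1 at 90% call rate
  res2 <- call_rate_filter(make_geno(m2), 0.95, 0.95)
  expect_equal(res2$removed$id, "S001")
  expect_equal(res2$removed$reason, "call_rate")

  # derived oracle: independent recount of the two-pass filter
  m3 <- m
  m3[runif(length(m3)) < 0.03] <- NA
  g3 <- make_geno(m3)
  res3 <- call_rate_filter(g3, 0.95, 0.95)
  keep_s <- rowMeans(!is.na(m3)) >= 0.95
  keep_v <- colMeans(!is.na(m3[keep_s, , drop = FALSE])) >= 0.95
  expect_setequal(res3$removed$id[res3$removed$type == "sample"],
                  sprintf("S%03d", which(!keep_s)))
  expect_setequal(res3$removed$id[res3$removed$type == "variant"],
                  sprintf("snp%03d", which(!keep_v)))
  # idempotence
  again <- call_rate_filter(res3$genotypes, 0.95, 0.95)
  expect_equal(nrow(again$removed), 0)
  expect_identical(again$genotypes$calls, res3$genotypes$calls)
})

test_that("HWE exact test matches enumeration oracles", {
  # (1,2,1): weights over het in {0,2,4} are 6/70, 48/70, 16/70 - modal table
  expect_equal(hwe_exact_test(1, 2, 1), 1.0)
  expect_equal(hwe_exact_test(20, 0, 0), 1.0) # monomorphic
  expect_equal(hwe_exact_test(57, 34, 9), oracle_hwe(57, 34, 9),
               tolerance = 1e-12)
  # spot configurations against the naive-factorial oracle
  for (cfg in list(c(5, 1, 5), c(10, 2, 0), c(3, 9, 3), c(0, 4, 8))) {
    expect_equal(hwe_exact_test(cfg[1], cfg[2], cfg[3]),
                 oracle_hwe(cfg[1], cfg[2], cfg[3]), tolerance = 1e-12)
  }
  expect_error(hwe_exact_test(-1, 2, 1), "non-negative")
})

test_that("HWE filter keeps equilibrium variants and drops all-het variants", {
  n <- 40
  hw <- c(rep(0L, 10), rep(1L, 20), rep(2L, 10)) # exact HW at maf 0.5
  allhet <- rep(1L, n)
  g <- make_geno(cbind(hw, allhet), ids = c("v_hw", "v_allhet"))
  samples <- tibble::tibble(sample_id = rownames(g$calls),
                            ethnicity = "Chinese")
  res <- hwe_filter(g, samples, "Chinese", alpha = 1e-6)
  expect_equal(colnames(res$genotypes$calls), "v_hw")
  expect_equal(res$removed$id, "v_allhet")
  # alpha = 1 boundary: monomorphic variants (p = 1) always retained
  mono <- make_geno(cbind(rep(0L, n), allhet), ids = c("v_mono", "v_allhet"))
  res1 <- hwe_filter(mono, samples, "Chinese", alpha = 1)
  expect_true("v_mono" %in% colnames(res1$genotypes$calls))
  expect_false("v_allhet" %in% colnames(res1$genotypes$calls))
  expect_error(hwe_filter(g, samples, "Martian"), "fewer than 2")
})

test_that("pairwise IBS matches a direct per-site recount", {
  m <- rbind(a = c(0L, 0L, 0L), b = c(2L, 2L, 2L), a2 = c(0L, 0L, 0L))
  res <- pairwise_ibs(make_geno(m))
  ab <- res[res$sample1 == "a" & res$sample2 == "b", ]
  expect_equal(ab$ibs, 0)
  dup <- res[res$sample1 == "a" & res$sample2 == "a2", ]
  expect_equal(dup$ibs, 1)
  expect_true(dup$flagged)

  set.seed(6)
  m2 <- matrix(sample(c(0:2, NA), 2 * 200, replace = TRUE,
                      prob = c(.3, .3, .3, .1)), 2, 200)
  res2 <- pairwise_ibs(make_geno(m2))
  d <- abs(m2[1, ] - m2[2, ])
  expect_equal(res2$ibs, mean((2 - d[!is.na(d)]) / 2))
  expect_equal(res2$n_shared, sum(!is.na(d)))

  # no shared non-missing variants: similarity undefined, reported as NA
  m3 <- rbind(x = c(1L, NA), y = c(NA, 1L))
  res3 <- pairwise_ibs(make_geno(m3))
  expect_true(is.na(res3$ibs))
  expect_false(res3$flagged)
})

test_that("heterozygosity outliers are flagged against mean +/- k SD", {
  m <- rbind(matrix(rep(c(0L, 2L), 50), 10, 10, byrow = TRUE),
             rep(1L, 10)) # one all-het sample
  rownames(m) <- sprintf("S%02d", 1:11)
  res <- heterozygosity_check(make_geno(m))
  expect_equal(res$sample_id[res$flagged], "S11")
  # identical samples: no flags
  same <- matrix(1L, 5, 8, dimnames = list(sprintf("S%d", 1:5), NULL))
  expect_false(any(heterozygosity_check(make_geno(same))$flagged))
  # independent mean/sd recomputation on a random cohort
  set.seed(7)
  m2 <- matrix(sample(0:2, 30 * 50, replace = TRUE), 30, 50)
  res2 <- heterozygosity_check(make_geno(m2), sd_multiplier = 2)
  het <- rowMeans(m2 == 1)
  expect_identical(res2$flagged,
                   unname(abs(het - mean(het)) > 2 * sd(het)))
})

test_that("PCA separates divergent strata and has a valid spectrum", {
  set.seed(9)
  n <- 60; p <- 150
  f1 <- runif(p, 0.1, 0.5)
  f2 <- plogis(qlogis(f1) + rnorm(p, 0, 1.5)) # strongly divergent stratum
  m <- rbind(
    t(vapply(1:n, function(i) rbinom(p, 2, f1), integer(p))),
    t(vapply(1:n, function(i) rbinom(p, 2, f2), integer(p)))
  )
  rownames(m) <- sprintf("S%03d", 1:(2 * n))
  pca <- genotype_pca(make_geno(m), 5)
  expect_true(all(diff(pca$eigenvalues) <= 1e-9))
  expect_true(all(pca$eigenvalues >= -1e-9))
  lab <- rep(c(0, 1), each = n)
  thr <- mean(tapply(pca$scores$PC1, lab, mean))
  acc <- mean((pca$scores$PC1 > thr) == (lab == which.max(
    tapply(pca$scores$PC1, lab, mean)) - 1))
  expect_gte(acc, 0.95)
})

test_that("PCA is invariant to sample duplication and variant order", {
  set.seed(10)
  m <- matrix(sample(0:2, 30 * 40, replace = TRUE), 30, 40)
  rownames(m) <- sprintf("S%03d", 1:30)
  g <- make_geno(m)
  pca <- genotype_pca(g, 3)
  # duplicating every sample leaves directions unchanged up to sign
  m2 <- rbind(m, m)
  rownames(m2) <- sprintf("S%03d", 1:60)
  pca2 <- genotype_pca(make_geno(m2), 3)
  for (j in 1:3) {
    cors <- abs(stats::cor(pca$loadings[, j], pca2$loadings[, j]))
    expect_gt(cors, 0.999)
  }
  # variant permutation: coordinates identical up to sign
  perm <- sample(40)
  pca3 <- genotype_pca(g[, perm], 3)
  for (j in 1:3) {
    expect_equal(abs(stats::cor(pca$scores[[paste0("PC", j)]],
                                pca3$scores[[paste0("PC", j)]])), 1,
                 tolerance = 1e-9)
  }
  expect_error(genotype_pca(make_geno(matrix(1L, 5, 3,
    dimnames = list(sprintf("S%d", 1:5), NULL)))), "zero variance")
})

test_that("run_qc composes removals with one primary reason each", {
  co <- generate_cohort(sim_config(seed = 21, missing_rate = 0.02,
                                   n_background_snps = 60))
  # duplicate one sample and inject a sex-mismatch flag
  g <- co$genotypes
  dup <- g$calls[1, , drop = FALSE]
  rownames(dup) <- "DUP01"
  g2 <- geno_matrix(rbind(g$calls, dup), g$variants)
  samples2 <- dplyr::bind_rows(
    co$samples, dplyr::mutate(co$samples[1, ], sample_id = "DUP01"))
  qc <- run_qc(g2, samples2, sex_mismatch = "S0002")
  expect_s3_class(qc, "qc_result")
  expect_true("S0002" %in% qc$report$id[qc$report$reason == "sex_mismatch"])
  expect_true("DUP01" %in% qc$report$id[qc$report$reason == "high_ibs"])
  # retained + removed samples partition the input
  removed_samples <- unique(qc$report$id[qc$report$type == "sample"])
  expect_equal(nrow(qc$genotypes$calls) + length(removed_samples),
               nrow(g2$calls))
  expect_false(anyDuplicated(qc$report$id) > 0)
})
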