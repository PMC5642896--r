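test_that("AUC matches the pairwise enumeration oracle and its symmetries", {
  y <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(roc_auc(c(0.9, 0.4, 0.5, 0.1), y), 0.75) # 3 wins, 1 loss
  expect_equal(roc_auc(c(2, 3, 0, 1), y), 1)
  expect_equal(roc_auc(rep(0.3, 4), y), 0.5)
  set.seed(12)
  s <- rnorm(40)
  yy <- rep(c(TRUE, FALSE), 20)
  expect_equal(roc_auc(s, yy), oracle_auc(s, yy))
  # invariance under strictly increasing transforms
  expect_equal(roc_auc(exp(2 * s), yy), roc_auc(s, yy))
  # complement identity for tie-free scores
  expect_equal(roc_auc(s, yy) + roc_auc(-s, yy), 1)
  expect_error(roc_auc(s, rep(TRUE, 40)), "Both classes")
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  s <- rnorm(60)
  y <- runif(60) < 0.4
  y[1:2] <- c(TRUE, FALSE)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(s, y), ref, tolerance = 1e-12)
})

test_that("risk models score samples and rank genetics above chance", {
  co <- generate_cohort(quick_config(seed = 71))
  calls <- infer_acetylator(co$genotypes)
  df <- dplyr::left_join(co$samples, calls[, c("sample_id", "exposure")],
                         by = "sample_id")
  m0 <- fit_risk_model(df, character(0), name = "intercept")
  expect_equal(stats::sd(m0$scores$score), 0)
  expect_equal(roc_auc(m0$scores$score, m0$scores$status == "case"), 0.5)
  m1 <- fit_risk_model(df, c("age", "sex", "ethnicity"))
  m2 <- fit_risk_model(df, c("age", "sex", "ethnicity", "exposure"))
  expect_equal(nrow(m1$scores), nrow(df))
  g2 <- glance(m2)
  expect_true(g2$auc > 0.5)
  t2 <- tidy(m2)
  expect_true("exposureTRUE" %in% t2$term)
  expect_error(fit_risk_model(df, "nonexistent"), "Missing feature")
})

test_that("adding a true genetic effect usually improves the AUC", {
  wins <- vapply(1:80, function(i) {
    co <- generate_cohort(quick_config(seed = 6000L + i))
    calls <- infer_acetylator(co$genotypes)
    df <- dplyr::left_join(co$samples, calls[, c("sample_id", "exposure")],
                           by = "sample_id")
    a <- suppressWarnings(fit_risk_model(df, c("age", "sex", "exposure")))
    b <- suppressWarnings(fit_risk_model(df, c("age", "sex")))
    roc_auc(a$scores$score, a$scores$status == "case") >
      roc_auc(b$scores$score, b$scores$status == "case")
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("risk scores sit at chance level against permuted labels", {
  co <- generate_cohort(quick_config(seed = 72))
  calls <- infer_acetylator(co$genotypes)
  df <- dplyr::left_join(co$samples, calls[, c("sample_id", "exposure")],
                         by = "sample_id")
  m <- fit_risk_model(df, c("age", "sex", "exposure"))
  set.seed(73)
  aucs <- vapply(1:200, function(i) {
    roc_auc(m$scores$score, sample(m$scores$status == "case"))
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("DeLong handles degenerate and symmetric cases", {
  set.seed(14)
  y <- rep(c(TRUE, FALSE), c(12, 18))
  s <- rnorm(30)
  same <- delong_test(s, s, y)
  expect_equal(same$delta, 0)
  expect_equal(same$p_value, 1)
  s2 <- rnorm(30)
  ab <- delong_test(s, s2, y)
  ba <- delong_test(s2, s, y)
  expect_equal(ab$delta, -ba$delta)
  expect_equal(ab$p_value, ba$p_value)
  expect_error(delong_test(s, s2[1:10], y), "align")
})

test_that("the placement-value variance matches a brute-force recount", {
  set.seed(15)
  y <- rep(c(TRUE, FALSE), c(10, 15))
  sa <- rnorm(25); sb <- 0.5 * sa + rnorm(25)
  res <- delong_test(sa, sb, y)
  # independent recount of placement values and their covariances
  plc <- function(s) {
    cases <- s[y]; ctrls <- s[!y]
    v10 <- sapply(cases, function(x) oracle_auc(c(x, ctrls),
                                                c(TRUE, rep(FALSE, 15))))
    v01 <- sapply(ctrls, function(x) oracle_auc(c(x, cases),
                                                c(FALSE, rep(TRUE, 10))))
    list(v10 = v10, v01 = v01)
  }
  pa <- plc(sa); pb <- plc(sb)
  va <- var(pa$v10 - pb$v10) / 10 + var(pa$v01 - pb$v01) / 15
  expect_equal(res$var_delta, va, tolerance = 1e-12)
})

test_that("DeLong agrees with the pROC reference on a random fixture", {
  skip_if_not_installed("pROC")
  set.seed(16)
  y <- rep(c(TRUE, FALSE), c(20, 30))
  lin <- rnorm(50) + 1.2 * y
  sa <- lin + rnorm(50, 0, 0.6)
  sb <- 0.5 * lin + rnorm(50, 0, 0.9)
  mine <- delong_test(sa, sb, y)
  ref <- pROC::roc.test(pROC::roc(y, sa, quiet = TRUE, direction = "<"),
                        pROC::roc(y, sb, quiet = TRUE, direction = "<"),
                        method = "delong")
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  expect_equal(mine$delta,
               as.numeric(ref$estimate[1] - ref$estimate[2]),
               tolerance = 1e-12)
})

test_that("the Youden-optimal threshold equals an exhaustive scan", {
  y <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  expect_equal(youden_optimal(c(3, 4, 5, 1, 2), y)$j, 1)
  expect_equal(youden_optimal(rep(1, 5), y)$j, 0)
  set.seed(17)
  s <- round(rnorm(40), 1) # ties on purpose
  yy <- runif(40) < 0.4
  yy[1:2] <- c(TRUE, FALSE)
  got <- youden_optimal(s, yy)
  # brute force over all candidate thresholds
  thr <- c(-Inf, sort(unique(s)), Inf)
  js <- sapply(thr, function(t) {
    mean((s >= t)[yy]) + mean((s < t)[!yy]) - 1
  })
  expect_equal(got$j, max(js), tolerance = 1e-12)
})

test_that("model comparison returns coherent AUC and Youden summaries", {
  co <- generate_cohort(quick_config(seed = 74))
  calls <- infer_acetylator(co$genotypes)
  df <- dplyr::left_join(co$samples, calls[, c("sample_id", "exposure")],
                         by = "sample_id")
  cmp <- compare_risk_models(df, clinical = c("age", "sex", "ethnicity"),
                             genetic = "exposure")
  expect_named(cmp$models, c("clinical", "clinical+exposure"))
  comps <- cmp$comparisons
  expect_true(all(comps$auc_a >= 0 & comps$auc_a <= 1))
  expect_true(all(comps$p_value >= 0 & comps$p_value <= 1))
  expect_equal(comps$delta, comps$auc_a - comps$auc_b, tolerance = 1e-12)
  td <- tidy(comps)
  expect_s3_class(td, "tbl_df")
})
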