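#' Fit a logistic risk model and score the cohort
#'
#' Fits case status on a declared feature set by maximum-likelihood
#' logistic regression and attaches in-sample fitted probabilities as risk
#' scores. Ethnicity enters as indicator variables with the largest
#' stratum as reference. Separation (a divergent coefficient) is flagged
#' with a warning; the model is still scored.
#'
#' @param samples Sample sheet tibble (needs `status` plus the feature
#'   columns).
#' @param features Character vector of column names to use as predictors
#'   (e.g. `c("age", "sex", "ethnicity")`, optionally plus `"exposure"` or
#'   a coded genotype column previously joined on).
#' @param name Model label.
#' @return A `risk_model` object: the glm `fit`, `scores` tibble
#'   (`sample_id`, `score`, `status`), `features`, `name`, `separation`.
#' @export
fit_risk_model <- function(samples, features = c("age", "sex", "ethnicity"),
                           name = paste(features, collapse = "+")) {
  missing_cols <- setdiff(features, names(samples))
  if (length(missing_cols)) {
    abort(sprintf("Missing feature column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  df <- samples[, c("sample_id", "status", features)]
  df <- df[stats::complete.cases(df), ]
  y <- df$status == "case"
  if (!any(y) || all(y)) abort("Need at least one case and one control.")
  if ("ethnicity" %in% features) {
    ref <- names(sort(table(df$ethnicity), decreasing = TRUE))[1]
    df$ethnicity <- stats::relevel(factor(df$ethnicity), ref = ref)
  }
  fml <- if (length(features)) {
    stats::reformulate(features, response = "status_case")
  } else {
    status_case ~ 1
  }
  df$status_case <- y
  fit <- suppressWarnings(glm(fml, data = df, family = binomial()))
  sep <- any(abs(coef(fit)[-1]) > 15, na.rm = TRUE)
  if (sep) warn(sprintf("Model '%s' shows separation; scores kept.", name))
  structure(list(
    fit = fit,
    scores = tibble(sample_id = df$sample_id,
                    score = as.numeric(stats::fitted(fit)),
                    status = df$status),
    features = features, name = name, separation = sep
  ), class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> %s; n = %d; AUC = %.3f\n", x$name,
              nrow(x$scores),
              roc_auc(x$scores$score, x$scores$status == "case")))
  invisible(x)
}

#' Area under the ROC curve
#'
#' The exact pairwise (Mann-Whitney) statistic:
#' `(#{case score > control score} + 0.5 * #ties) / (n_case * n_control)`.
#'
#' @param scores Numeric risk scores.
#' @param labels Logical case indicator (or `"case"`/`"control"`).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- if (is.logical(labels)) labels else labels == "case"
  ok <- !is.na(scores) & !is.na(y)
  scores <- scores[ok]
  y <- y[ok]
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) abort("Both classes must be present.")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Sensitivity/specificity at every distinct score threshold (positive
#' call: score >= threshold), with infinite sentinels at the ends.
#'
#' @param scores Numeric risk scores.
#' @param labels Logical case indicator (or `"case"`/`"control"`).
#' @return Tibble (`threshold`, `sensitivity`, `specificity`) with class
#'   `roc_points`.
#' @export
roc_points <- function(scores, labels) {
  y <- if (is.logical(labels)) labels else labels == "case"
  thr <- c(-Inf, sort(unique(scores)), Inf)
  out <- purrr::map_dfr(thr, function(t) {
    pos <- scores >= t
    tibble(threshold = t,
           sensitivity = mean(pos[y]),
           specificity = mean(!pos[!y]))
  })
  class(out) <- c("roc_points", class(out))
  out
}

#' Youden-optimal operating point
#'
#' Scans every distinct score threshold, returns the maximizer of
#' `J = sensitivity + specificity - 1`; ties are broken towards higher
#' specificity (higher threshold).
#'
#' @param scores Numeric risk scores.
#' @param labels Logical case indicator (or `"case"`/`"control"`).
#' @return One-row tibble (`threshold`, `sensitivity`, `specificity`, `j`).
#' @export
youden_optimal <- function(scores, labels) {
  pts <- roc_points(scores, labels)
  pts$j <- pts$sensitivity + pts$specificity - 1
  best <- pts %>%
    filter(.data$j >= max(.data$j) - 1e-12) %>%
    arrange(dplyr::desc(.data$specificity), dplyr::desc(.data$threshold)) %>%
    dplyr::slice(1)
  tibble(threshold = best$threshold, sensitivity = best$sensitivity,
         specificity = best$specificity, j = best$j)
}

#' DeLong's test for two correlated AUCs
#'
#' Nonparametric comparison of the AUCs of two risk models scored on the
#' same samples, via placement values: for each case its mean win rate
#' over controls, and for each control its mean loss rate against cases
#' (ties count one half). The variance of the paired AUC difference comes
#' from the empirical covariance of the placement values across models;
#' `z = dAUC / sqrt(var)` is referred to the standard normal (two-sided).
#' Identical scores give `dAUC = 0`, `p = 1`.
#'
#' @param scores_a,scores_b Scores of models A and B on the same samples.
#' @param labels Logical case indicator (or `"case"`/`"control"`).
#' @param name_a,name_b Model labels.
#' @return One-row `roc_comparison` tibble (`auc_a`, `auc_b`, `delta`,
#'   `var_delta`, `z`, `p_value`, Youden J per model).
#' @export
delong_test <- function(scores_a, scores_b, labels,
                        name_a = "A", name_b = "B") {
  y <- if (is.logical(labels)) labels else labels == "case"
  if (length(scores_a) != length(y) || length(scores_b) != length(y)) {
    abort("Scores and labels must align.")
  }
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) abort("Both classes must be present.")
  placements <- function(s) {
    cases <- s[y]
    ctrls <- s[!y]
    v10 <- vapply(cases, function(x)
      mean((x > ctrls) + 0.5 * (x == ctrls)), numeric(1))
    v01 <- vapply(ctrls, function(x)
      mean((cases > x) + 0.5 * (cases == x)), numeric(1))
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  pa <- placements(scores_a)
  pb <- placements(scores_b)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  delta <- pa$auc - pb$auc
  if (var_delta <= 0) {
    z <- 0
    p <- 1
  } else {
    z <- delta / sqrt(var_delta)
    p <- 2 * pnorm(-abs(z))
  }
  ja <- youden_optimal(scores_a, y)
  jb <- youden_optimal(scores_b, y)
  out <- tibble(
    model_a = name_a, model_b = name_b,
    auc_a = pa$auc, auc_b = pb$auc,
    delta = delta, var_delta = max(var_delta, 0), z = z, p_value = p,
    youden_a = ja$j, youden_b = jb$j
  )
  class(out) <- c("roc_comparison", class(out))
  out
}

#' Compare clinical and clinical-plus-genetic risk models
#'
#' Fits a clinical baseline model and one augmented model per supplied
#' genetic feature column, then compares each augmented model to the
#' baseline with [delong_test()] on the shared complete-case samples.
#'
#' @param samples Sample sheet already joined with the genetic feature
#'   columns (e.g. `exposure`, `rs1495741_aa`).
#' @param clinical Character vector of clinical feature columns.
#' @param genetic Character vector of genetic feature columns to add one
#'   at a time.
#' @return List with `models` (named list of `risk_model`) and
#'   `comparisons` (tibble of DeLong results vs the clinical model).
#' @export
compare_risk_models <- function(samples,
                                clinical = c("age", "sex", "ethnicity"),
                                genetic = "exposure") {
  keep <- stats::complete.cases(samples[, c(clinical, genetic), drop = FALSE])
  df <- samples[keep, ]
  base <- fit_risk_model(df, clinical, name = "clinical")
  models <- list(clinical = base)
  comps <- purrr::map_dfr(genetic, function(g) {
    m <- fit_risk_model(df, c(clinical, g),
                        name = paste0("clinical+", g))
    models[[m$name]] <<- m
    delong_test(m$scores$score, base$scores$score,
                base$scores$status == "case",
                name_a = m$name, name_b = "clinical")
  })
  list(models = models, comparisons = comps)
}
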