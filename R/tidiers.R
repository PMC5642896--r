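#' Tidy a fitted risk model
#'
#' Coefficient-level summary of the underlying logistic fit, with odds
#' ratios and Wald 95% confidence limits.
#'
#' @param x A `risk_model` from [fit_risk_model()].
#' @param ... Unused.
#' @return Tibble (`term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`, `odds_ratio`, `ci_low`, `ci_high`).
#' @export
tidy.risk_model <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble(
    term = rownames(co),
    estimate = co[, "Estimate"],
    std_error = co[, "Std. Error"],
    statistic = co[, "z value"],
    p_value = co[, "Pr(>|z|)"],
    odds_ratio = exp(co[, "Estimate"]),
    ci_low = exp(co[, "Estimate"] - 1.96 * co[, "Std. Error"]),
    ci_high = exp(co[, "Estimate"] + 1.96 * co[, "Std. Error"])
  )
}

#' One-row summary of a fitted risk model
#'
#' @param x A `risk_model`.
#' @param ... Unused.
#' @return Tibble (`name`, `n`, `n_cases`, `auc`, `youden_j`, `aic`,
#'   `separation`).
#' @export
glance.risk_model <- function(x, ...) {
  y <- x$scores$status == "case"
  tibble(
    name = x$name, n = nrow(x$scores), n_cases = sum(y),
    auc = roc_auc(x$scores$score, y),
    youden_j = youden_optimal(x$scores$score, y)$j,
    aic = stats::AIC(x$fit),
    separation = x$separation
  )
}

#' Tidy a DeLong ROC comparison
#'
#' @param x A `roc_comparison` from [delong_test()].
#' @param ... Unused.
#' @return The comparison as a plain tibble.
#' @export
tidy.roc_comparison <- function(x, ...) {
  as_tibble(unclass(x))
}

#' Tidy a genotype PCA
#'
#' @param x A `geno_pca` from [genotype_pca()].
#' @param ... Unused.
#' @return Tibble (`component`, `eigenvalue`, `prop_variance`).
#' @export
tidy.geno_pca <- function(x, ...) {
  tibble(
    component = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    prop_variance = x$eigenvalues / sum(x$eigenvalues)
  )
}
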