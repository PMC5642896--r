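#' Build the exposure 2x2 table for a cohort
#'
#' Cross-tabulates an exposure call (e.g. slow-acetylator status) against
#' case/control status. Samples with a missing exposure are excluded.
#'
#' @param exposure Tibble (`sample_id`, `exposure` logical).
#' @param samples Sample sheet with `sample_id` and `status`.
#' @return One-row tibble of counts (`exposed_cases`, `exposed_controls`,
#'   `unexposed_cases`, `unexposed_controls`) with class `exposure_table`.
#' @export
exposure_table <- function(exposure, samples) {
  df <- left_join(samples[, c("sample_id", "status")], exposure,
                  by = "sample_id") %>%
    filter(!is.na(.data$exposure))
  if (!nrow(df)) abort("Empty cohort.")
  y <- df$status == "case"
  if (sum(y) == 0 || sum(!y) == 0) abort("Need both cases and controls.")
  e <- df$exposure
  new_exposure_table(sum(e & y), sum(e & !y), sum(!e & y), sum(!e & !y))
}

#' Construct an exposure table from counts
#'
#' @param exposed_cases,exposed_controls,unexposed_cases,unexposed_controls
#'   Non-negative counts.
#' @return One-row `exposure_table` tibble.
#' @export
new_exposure_table <- function(exposed_cases, exposed_controls,
                               unexposed_cases, unexposed_controls) {
  counts <- c(exposed_cases, exposed_controls, unexposed_cases,
              unexposed_controls)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Counts must be non-negative integers.")
  }
  out <- tibble(exposed_cases = exposed_cases,
                exposed_controls = exposed_controls,
                unexposed_cases = unexposed_cases,
                unexposed_controls = unexposed_controls)
  class(out) <- c("exposure_table", class(out))
  out
}

#' Sensitivity and specificity of an exposure as a test
#'
#' Sensitivity is the exposed fraction of cases; specificity the unexposed
#' fraction of controls. Values are exact fractions carried at full
#' precision; rounding happens only in report formatting.
#'
#' @param tab An [exposure_table()].
#' @return One-row tibble (`sensitivity`, `specificity`, margins).
#' @export
sens_spec <- function(tab) {
  n_cases <- tab$exposed_cases + tab$unexposed_cases
  n_controls <- tab$exposed_controls + tab$unexposed_controls
  if (n_cases == 0 || n_controls == 0) abort("Zero case or control margin.")
  tibble(sensitivity = tab$exposed_cases / n_cases,
         specificity = tab$unexposed_controls / n_controls,
         n_cases = n_cases, n_controls = n_controls)
}

#' Predictive values by Bayes' theorem
#'
#' `PPV = sens * prev / (sens * prev + (1 - spec) * (1 - prev))` and
#' `NPV = spec * (1 - prev) / ((1 - sens) * prev + spec * (1 - prev))` -
#' the post-test disease probabilities at an assumed population prevalence,
#' independent of the case-control sampling fractions.
#'
#' @param sensitivity,specificity,prevalence Proportions in `[0, 1]`.
#' @return One-row tibble (`prevalence`, `ppv`, `npv`, `flag`).
#' @export
bayes_predictive_values <- function(sensitivity, specificity, prevalence) {
  assert_prob(sensitivity, "sensitivity")
  assert_prob(specificity, "specificity")
  assert_prob(prevalence, "prevalence")
  den_p <- sensitivity * prevalence + (1 - specificity) * (1 - prevalence)
  den_n <- (1 - sensitivity) * prevalence + specificity * (1 - prevalence)
  tibble(
    prevalence = prevalence,
    ppv = ifelse(den_p > 0, sensitivity * prevalence / den_p, NA_real_),
    npv = ifelse(den_n > 0, specificity * (1 - prevalence) / den_n, NA_real_),
    flag = ifelse(den_p > 0 & den_n > 0, NA_character_, "division_by_zero")
  )
}

#' Predictive values across a prevalence grid
#'
#' @param sensitivity,specificity Test characteristics.
#' @param prevalences Numeric grid in `[0, 1]` (default 5-20% by 1%).
#' @return Tibble, one row per prevalence, with class `prevalence_sweep`.
#' @export
prevalence_sweep <- function(sensitivity, specificity,
                             prevalences = seq(0.05, 0.20, by = 0.01)) {
  if (!length(prevalences)) abort("Empty prevalence grid.")
  out <- bayes_predictive_values(sensitivity, specificity, prevalences)
  class(out) <- c("prevalence_sweep", class(out))
  out
}

#' Population attributable fraction
#'
#' Two estimators: `"incidence"` computes `(IP_t - IP_o) / IP_t` from the
#' incidence proportions in the total population and in the unexposed;
#' `"case_based"` computes `p_c * (OR - 1) / OR` from the exposed fraction
#' among cases and the odds ratio (a rare-disease approximation using the
#' OR in place of the risk ratio).
#'
#' @param method `"case_based"` or `"incidence"`.
#' @param exposed_case_fraction,odds_ratio Inputs for `case_based`.
#' @param ip_total,ip_unexposed Inputs for `incidence`.
#' @return PAF (scalar, in `(-Inf, 1]`).
#' @export
paf <- function(method = c("case_based", "incidence"),
                exposed_case_fraction = NULL, odds_ratio = NULL,
                ip_total = NULL, ip_unexposed = NULL) {
  method <- match.arg(method)
  if (method == "case_based") {
    if (is.null(exposed_case_fraction) || is.null(odds_ratio)) {
      abort("case_based needs `exposed_case_fraction` and `odds_ratio`.")
    }
    if (odds_ratio <= 0) abort("`odds_ratio` must be positive.")
    return(exposed_case_fraction * (odds_ratio - 1) / odds_ratio)
  }
  if (is.null(ip_total) || is.null(ip_unexposed)) {
    abort("incidence needs `ip_total` and `ip_unexposed`.")
  }
  if (ip_total <= 0) abort("`ip_total` must be positive.")
  (ip_total - ip_unexposed) / ip_total
}

#' Number needed to test
#'
#' Reciprocal of the risk difference between exposed and unexposed
#' (`NNT = 1 / (risk_exposed - risk_unexposed)`); undefined when the
#' difference is not positive.
#'
#' @param risk_exposed,risk_unexposed Risks in `[0, 1]`.
#' @return One-row tibble (`arr`, `nnt`, `defined`).
#' @export
nnt <- function(risk_exposed, risk_unexposed) {
  assert_prob(risk_exposed, "risk_exposed")
  assert_prob(risk_unexposed, "risk_unexposed")
  arr <- risk_exposed - risk_unexposed
  tibble(arr = arr,
         nnt = ifelse(arr > 0, 1 / arr, NA_real_),
         defined = arr > 0)
}

#' Youden's J statistic
#'
#' `J = sensitivity + specificity - 1`.
#'
#' @param sensitivity,specificity Proportions in `[0, 1]`.
#' @return J in `[-1, 1]`.
#' @export
youden <- function(sensitivity, specificity) {
  assert_prob(sensitivity, "sensitivity")
  assert_prob(specificity, "specificity")
  sensitivity + specificity - 1
}

#' Full clinical-validity calculus for one exposure definition
#'
#' From an exposure 2x2 table and an assumed prevalence: sensitivity,
#' specificity, Bayes PPV/NPV, the risks in exposed (`= PPV`) and
#' unexposed (`= 1 - NPV`), absolute risk difference and NNT, Youden's J,
#' and both PAF estimators (case-based, using the table's sample odds
#' ratio unless `odds_ratio` overrides it with a covariate-adjusted value,
#' and the incidence formula with `IP_t = prevalence` and
#' `IP_o = 1 - NPV`).
#'
#' @param tab An [exposure_table()].
#' @param prevalence Assumed outcome prevalence.
#' @param odds_ratio Optional adjusted odds ratio for the case-based PAF.
#' @param label Exposure label carried into the row.
#' @return One-row `validity_measures` tibble.
#' @examples
#' tab <- new_exposure_table(18, 17, 6, 62)
#' clinical_validity(tab, prevalence = 0.10, odds_ratio = 9.98)
#' @export
clinical_validity <- function(tab, prevalence = 0.10, odds_ratio = NULL,
                              label = "exposure") {
  ss <- sens_spec(tab)
  pv <- bayes_predictive_values(ss$sensitivity, ss$specificity, prevalence)
  risk_exposed <- pv$ppv
  risk_unexposed <- 1 - pv$npv
  nn <- nnt(risk_exposed, risk_unexposed)
  or <- odds_ratio %||%
    ((tab$exposed_cases * tab$unexposed_controls) /
       (tab$exposed_controls * tab$unexposed_cases))
  out <- tibble(
    exposure = label,
    sensitivity = ss$sensitivity, specificity = ss$specificity,
    prevalence = prevalence, ppv = pv$ppv, npv = pv$npv,
    risk_exposed = risk_exposed, risk_unexposed = risk_unexposed,
    ip_total = prevalence,
    arr = nn$arr, nnt = nn$nnt,
    paf_case_based = paf("case_based",
                         exposed_case_fraction = ss$sensitivity,
                         odds_ratio = or),
    paf_incidence = paf("incidence", ip_total = prevalence,
                        ip_unexposed = risk_unexposed),
    odds_ratio = or,
    youden_j = youden(ss$sensitivity, ss$specificity)
  )
  class(out) <- c("validity_measures", class(out))
  out
}
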