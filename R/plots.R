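#' Plot predictive values across prevalence
#'
#' @param object A `prevalence_sweep` from [prevalence_sweep()].
#' @param ... Unused.
#' @return A ggplot: PPV and NPV against assumed prevalence.
#' @export
autoplot.prevalence_sweep <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(unclass(object)),
                            c("ppv", "npv"),
                            names_to = "measure", values_to = "value")
  ggplot(df, aes(x = .data$prevalence, y = .data$value,
                 colour = toupper(.data$measure))) +
    geom_line() +
    geom_point(size = 1) +
    scale_y_continuous(limits = c(0, 1), labels = function(x) 100 * x) +
    labs(x = "Assumed prevalence", y = "Predictive value (%)",
         colour = NULL) +
    theme_minimal()
}

#' Plot an ROC curve
#'
#' @param object A `roc_points` tibble from [roc_points()].
#' @param ... Unused.
#' @return A ggplot of the ROC curve with the chance diagonal.
#' @export
autoplot.roc_points <- function(object, ...) {
  ggplot(as_tibble(unclass(object)),
         aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    geom_step(direction = "vh") +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    coord_equal() +
    labs(x = "1 - specificity", y = "Sensitivity") +
    theme_minimal()
}

#' Plot PCA scores coloured by a sample grouping
#'
#' @param pca A `geno_pca` from [genotype_pca()].
#' @param samples Sample sheet tibble; `colour` names one of its columns.
#' @param colour Column used for point colour (default ethnicity).
#' @return A ggplot of PC1 vs PC2.
#' @export
plot_pca_scores <- function(pca, samples, colour = "ethnicity") {
  df <- left_join(pca$scores, samples, by = "sample_id")
  ggplot(df, aes(x = .data$PC1, y = .data$PC2,
                 colour = .data[[colour]])) +
    geom_point() +
    labs(colour = colour) +
    theme_minimal()
}

#' Plot risk allele frequency by DILI grade
#'
#' @param freq_tbl Output of [risk_allele_freq_by_grade()], or several
#'   bound together with a `label` column.
#' @return A ggplot of frequency against grade.
#' @export
plot_grade_trend <- function(freq_tbl) {
  has_label <- "label" %in% names(freq_tbl)
  p <- ggplot(freq_tbl, aes(x = factor(.data$grade), y = .data$freq,
                            group = if (has_label) .data$label else 1)) +
    geom_col(aes(fill = if (has_label) .data$label else NULL),
             position = "dodge") +
    labs(x = "DILI grade", y = "Risk allele / exposure frequency",
         fill = NULL) +
    theme_minimal()
  p
}
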