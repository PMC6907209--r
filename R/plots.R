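#' @import ggplot2
NULL

#' Histogram of per-repeat cross-validated accuracy
#' @param object A `cv_accuracy`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cv_accuracy <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$r)) +
    geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    geom_vline(xintercept = object$mean_r, linetype = 2) +
    labs(x = "per-repeat Pearson r (predicted vs chronological age)",
         y = "repeats",
         title = sprintf("%d-fold CV accuracy: mean r = %.2f [%.2f, %.2f]",
                         object$k, object$mean_r, object$ci_low, object$ci_high)) +
    theme_minimal()
}

#' DDI distribution coloured by developmental subgroup
#' @param object A `ddi_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ddi_result <- function(object, ...) {
  ggplot(object, aes(x = .data$ddi, fill = .data$subgroup)) +
    geom_histogram(bins = 30, colour = "white") +
    geom_vline(xintercept = c(-1, -0.2, 0.2, 1), linetype = 3) +
    labs(x = "Developmental Deviation Index (z)", y = "participants",
         fill = "subgroup") +
    theme_minimal()
}

#' Regional maturation profile
#'
#' Age-correlation by region, faceted by metric and coloured by tissue
#' class, the tabular stand-in for a surface rendering.
#'
#' @param correlations Output of [regional_age_correlation()] (rows from
#'   several metrics may be bound together).
#' @return A ggplot.
#' @export
plot_maturation <- function(correlations) {
  ggplot(correlations, aes(x = .data$r, y = stats::reorder(.data$region, .data$r),
                           colour = .data$tissue)) +
    geom_point(size = 0.8) +
    geom_vline(xintercept = 0, linetype = 2) +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "Pearson r with age", y = NULL, colour = "tissue") +
    theme_minimal() +
    theme(axis.text.y = element_blank())
}

#' Effect-size robustness across DDI thresholds
#' @param sweep A `sweep_result` from [threshold_sweep()].
#' @return A ggplot of CLES against per-group size.
#' @export
plot_threshold_sweep <- function(sweep) {
  ggplot(sweep, aes(x = .data$group_size, y = .data$cles)) +
    geom_line() +
    geom_point(aes(shape = .data$p < 0.05)) +
    geom_hline(yintercept = 0.5, linetype = 2) +
    labs(x = "participants per extreme subgroup",
         y = "P(severity higher in Delayed)",
         shape = "p < 0.05") +
    theme_minimal()
}

#' Severity by developmental subgroup
#' @param ddi A `ddi_result`.
#' @param severity Severity scores matched to the rows of `ddi`.
#' @return A ggplot boxplot over the three named subgroups.
#' @export
plot_severity_by_subgroup <- function(ddi, severity) {
  dat <- dplyr::mutate(tibble::as_tibble(ddi), severity = severity) |>
    dplyr::filter(.data$subgroup != "Unassigned", !is.na(severity))
  ggplot(dat, aes(x = .data$subgroup, y = .data$severity, fill = .data$subgroup)) +
    geom_boxplot(outlier.shape = NA) +
    geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    labs(x = NULL, y = "symptom severity (ADOS CSS)") +
    guides(fill = "none") +
    theme_minimal()
}
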