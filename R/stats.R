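#' Fisher-transform confidence interval for a correlation
#'
#' Maps `r` through `atanh`, builds a normal interval with standard error
#' `1 / sqrt(n - 3)`, and maps the bounds back through `tanh`. The same
#' recipe is applied to Pearson and Spearman coefficients.
#'
#' @param r Correlation coefficient(s), strictly inside (-1, 1).
#' @param n Sample size(s), greater than 3.
#' @param confidence Coverage, default 0.95.
#' @return Tibble with columns `ci_low`, `ci_high` (one row per `r`).
#' @export
fisher_ci <- function(r, n, confidence = 0.95) {
  if (any(n <= 3)) abort("fisher_ci needs n > 3")
  if (any(abs(r) >= 1)) abort("fisher_ci needs |r| < 1")
  z <- atanh(r)
  half <- qnorm(1 - (1 - confidence) / 2) / sqrt(n - 3)
  tibble::tibble(ci_low = tanh(z - half), ci_high = tanh(z + half))
}

#' Correlation with Fisher-transform confidence interval
#'
#' @param x,y Numeric vectors; pairs with missing values are dropped.
#' @param method `"pearson"` or `"spearman"` (average ranks for ties).
#' @param confidence CI coverage.
#' @return One-row tibble: `method`, `r`, `n`, `p` (two-sided), `ci_low`,
#'   `ci_high`.
#' @export
cor_with_ci <- function(x, y, method = c("pearson", "spearman"), confidence = 0.95) {
  method <- match.arg(method)
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n <= 3) abort("need more than 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("correlation undefined for constant input")
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  r <- unname(ct$estimate)
  ci <- if (abs(r) < 1) fisher_ci(r, n, confidence) else
    tibble::tibble(ci_low = r, ci_high = r)
  tibble::tibble(method = method, r = r, n = n, p = ct$p.value,
                 ci_low = ci$ci_low, ci_high = ci$ci_high)
}

#' @rdname cor_with_ci
#' @export
spearman_with_ci <- function(x, y, confidence = 0.95) {
  cor_with_ci(x, y, method = "spearman", confidence = confidence)
}

#' Cohen's d with pooled standard deviation
#'
#' `(mean1 - mean2) / s_pooled`, pooling variances with `n - 1` weights.
#' Positive values mean group 1 lies higher.
#'
#' @param group1,group2 Numeric vectors (missing values dropped), each with
#'   at least 2 observations.
#' @return The effect size `d`.
#' @seealso [cohens_d_from_summary()] for the summary-statistic form.
#' @export
cohens_d <- function(group1, group2) {
  group1 <- group1[!is.na(group1)]; group2 <- group2[!is.na(group2)]
  if (length(group1) < 2 || length(group2) < 2) abort("each group needs n >= 2")
  cohens_d_from_summary(mean(group1), sd(group1), length(group1),
                        mean(group2), sd(group2), length(group2))
}

#' Cohen's d from summary statistics
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return The pooled-SD effect size `d`.
#' @export
cohens_d_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  pooled <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (pooled == 0) abort("zero pooled standard deviation")
  (mean1 - mean2) / pooled
}

#' Common-language effect size
#'
#' The probability that a randomly drawn member of `group1` exceeds a
#' randomly drawn member of `group2`, counting ties as half:
#' `(#(g1 > g2) + 0.5 * #(g1 = g2)) / (n1 * n2)`. Equals the Mann-Whitney
#' `U` of [mann_whitney()] divided by `n1 * n2`, so
#' `cles(a, b) + cles(b, a) = 1`.
#'
#' @param group1,group2 Numeric vectors (missing values dropped).
#' @return A probability in `[0, 1]`.
#' @export
cles <- function(group1, group2) {
  group1 <- group1[!is.na(group1)]; group2 <- group2[!is.na(group2)]
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 1 || n2 < 1) abort("each group needs n >= 1")
  # rank formulation: sum of combined ranks of group1 minus its minimum
  # equals wins + half-ties over all cross pairs
  r <- rank(c(group1, group2))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u / (n1 * n2)
}

#' Mann-Whitney test
#'
#' `U` counts the pairs in which `group1` exceeds `group2` plus half of
#' the tied pairs, so `U / (n1 * n2)` is exactly [cles()]. The p-value is
#' two-sided: exact when there are no ties and `n1 * n2 <= 400`, otherwise
#' the tie-corrected normal approximation (no continuity correction).
#'
#' @param group1,group2 Numeric vectors.
#' @return One-row tibble `u`, `p`, `n1`, `n2`.
#' @export
mann_whitney <- function(group1, group2) {
  group1 <- group1[!is.na(group1)]; group2 <- group2[!is.na(group2)]
  n1 <- length(group1); n2 <- length(group2)
  u <- cles(group1, group2) * n1 * n2
  has_ties <- anyDuplicated(c(group1, group2)) > 0
  exact <- !has_ties && n1 * n2 <= 400
  p <- suppressWarnings(
    wilcox.test(group1, group2, exact = exact, correct = FALSE)$p.value
  )
  tibble::tibble(u = u, p = p, n1 = n1, n2 = n2)
}

#' Kruskal-Wallis rank test across groups
#' @param groups List of numeric vectors (at least two non-empty groups).
#' @return One-row tibble `h` (tie-corrected statistic), `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- purrr::map(groups, ~ .x[!is.na(.x)])
  if (length(groups) < 2 || any(lengths(groups) < 1)) {
    abort("need at least two non-empty groups")
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(values)) == 1L) {
    return(tibble::tibble(h = 0, df = length(groups) - 1L, p = 1))
  }
  kt <- kruskal.test(values, g)
  tibble::tibble(h = unname(kt$statistic), df = unname(kt$parameter),
                 p = kt$p.value)
}

#' Pearson chi-square test on a 2x2 table (no continuity correction)
#' @param counts A 2x2 matrix of non-negative counts with positive margins.
#' @return One-row tibble `chi2`, `df`, `p`.
#' @export
chi2_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) abort("counts must be 2x2")
  if (any(counts < 0)) abort("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("all margins must be positive")
  }
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  tibble::tibble(chi2 = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value)
}

#' Proportional-odds ordinal regression of severity on covariates
#'
#' Fits the cumulative-logit model
#' `logit P(Y <= k) = zeta_k - x' beta` by maximum likelihood (via
#' [MASS::polr()]), the usual robustness model for an ordinal severity
#' outcome: `Severity ~ DDI + Motion + IQ`. Per-covariate p-values are
#' two-sided Wald tests.
#'
#' @param severity Ordinal outcome (integers, e.g. ADOS CSS 1-10); at
#'   least two distinct levels must be observed.
#' @param covariates Data frame of numeric covariates (rows matched to
#'   `severity`); rows with any missing value are dropped.
#' @return An `ordinal_fit` object; see [tidy.ordinal_fit()].
#' @export
ordinal_fit <- function(severity, covariates) {
  covariates <- tibble::as_tibble(covariates)
  keep <- complete.cases(severity, covariates)
  severity <- severity[keep]
  covariates <- covariates[keep, , drop = FALSE]
  if (length(unique(severity)) < 2) abort("severity must show at least two levels")
  dat <- dplyr::bind_cols(tibble::tibble(.y = ordered(severity)), covariates)
  fml <- stats::as.formula(paste(".y ~", paste(names(covariates), collapse = " + ")))
  fit <- tryCatch(
    suppressWarnings(MASS::polr(fml, data = dat, Hess = TRUE)),
    error = function(e) abort(paste0(
      "ordinal model failed to converge (possible complete separation): ",
      conditionMessage(e)))
  )
  sm <- suppressWarnings(summary(fit))
  tab <- sm$coefficients
  k <- length(coef(fit))
  coefs <- tibble::tibble(
    term = rownames(tab)[seq_len(k)],
    estimate = tab[seq_len(k), "Value"],
    std_error = tab[seq_len(k), "Std. Error"],
    statistic = tab[seq_len(k), "t value"],
    p = 2 * pnorm(-abs(tab[seq_len(k), "t value"]))
  )
  thresholds <- fit$zeta
  if (is.unsorted(thresholds, strictly = TRUE)) {
    abort("fitted thresholds are not strictly increasing")
  }
  structure(list(coefficients = coefs, thresholds = thresholds,
                 n = length(severity), fit = fit),
            class = "ordinal_fit")
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat(sprintf("<ordinal_fit> proportional-odds model, n = %d, %d thresholds\n",
              x$n, length(x$thresholds)))
  print(x$coefficients)
  invisible(x)
}

#' Tidy an ordinal severity model
#' @param x An `ordinal_fit`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate`, `std_error`, `statistic`, `p`.
#' @exportS3Method generics::tidy
tidy.ordinal_fit <- function(x, ...) x$coefficients

#' One-row summary of an ordinal severity model
#' @param x An `ordinal_fit`.
#' @param ... Unused.
#' @return Tibble `n`, `n_thresholds`, `logLik`, `aic`.
#' @exportS3Method generics::glance
glance.ordinal_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_thresholds = length(x$thresholds),
                 logLik = as.numeric(stats::logLik(x$fit)),
                 aic = stats::AIC(x$fit))
}

#' Two-group effect-size report for an ordinal outcome
#'
#' Convenience bundle of the battery used to compare severity between two
#' developmental subgroups: pooled-SD Cohen's d (given for completeness;
#' severity is ordinal), common-language effect size, and the Mann-Whitney
#' test.
#'
#' @param group1,group2 Numeric vectors.
#' @return One-row tibble `d`, `cles`, `u`, `p_u`, `n1`, `n2`.
#' @export
effect_size_report <- function(group1, group2) {
  mw <- mann_whitney(group1, group2)
  tibble::tibble(d = cohens_d(group1, group2),
                 cles = mw$u / (mw$n1 * mw$n2),
                 u = mw$u, p_u = mw$p, n1 = mw$n1, n2 = mw$n2)
}
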