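#' Per-region correlation between a brain metric and age
#'
#' Pearson correlation of each region's values with chronological age,
#' with two-sided p-values from the exact t reference distribution
#' (`n - 2` degrees of freedom) and Benjamini-Hochberg q-values computed
#' over the regions of this metric (the FDR family is one metric).
#' Zero-variance regions are flagged (`r` missing) and excluded from the
#' FDR family.
#'
#' @param table A `metric_table`.
#' @param ages Chronological ages in years, one per table row.
#' @return Tibble `metric`, `region`, `hemisphere`, `tissue`, `r`, `n`,
#'   `p`, `q`.
#' @export
regional_age_correlation <- function(table, ages) {
  stopifnot(inherits(table, "metric_table"))
  vals <- table_values(table)
  if (length(ages) != nrow(vals)) abort("ages must match table rows")
  if (nrow(vals) < 4) abort("need at least 4 participants")
  regions <- table_regions(table)
  res <- purrr::map(seq_len(ncol(vals)), function(j) {
    v <- vals[, j]
    if (sd(v) == 0) {
      return(tibble::tibble(r = NA_real_, p = NA_real_))
    }
    ct <- cor.test(v, ages, method = "pearson")
    tibble::tibble(r = unname(ct$estimate), p = ct$p.value)
  }) |> purrr::list_rbind()
  out <- tibble::tibble(
    metric = table_metric(table),
    region = regions$name,
    hemisphere = regions$hemisphere,
    tissue = regions$tissue,
    r = res$r, n = nrow(vals), p = res$p,
    q = NA_real_
  )
  ok <- !is.na(out$p)
  out$q[ok] <- p.adjust(out$p[ok], method = "BH")
  out
}

#' Regions whose age correlation is significant in both groups
#'
#' Region-level comparison of maturation between groups is only meaningful
#' where an age effect exists in both, so the comparison set is restricted
#' to regions with unadjusted `p < alpha` in both correlation tables.
#'
#' @param tdc,asd Correlation tibbles from [regional_age_correlation()]
#'   over the same metric/region universe.
#' @param alpha Unadjusted significance level, default 0.05.
#' @return Tibble `metric`, `region` of jointly significant regions.
#' @export
joint_significant_regions <- function(tdc, asd, alpha = 0.05) {
  key <- function(x) paste(x$metric, x$region)
  if (!identical(sort(key(tdc)), sort(key(asd)))) {
    abort("the two correlation tables must cover the same metric/region universe")
  }
  asd <- asd[match(key(tdc), key(asd)), ]
  sel <- !is.na(tdc$p) & !is.na(asd$p) & tdc$p < alpha & asd$p < alpha
  tibble::tibble(metric = tdc$metric[sel], region = tdc$region[sel])
}

#' Compare two independent correlations (Fisher r-to-z)
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-sided normal p-value.
#'
#' @param r1,n1 First correlation and its sample size (`n1 > 3`).
#' @param r2,n2 Second correlation and its sample size.
#' @return Tibble `z`, `p` (vectorised over the inputs).
#' @export
compare_correlations <- function(r1, n1, r2, n2) {
  if (any(abs(r1) >= 1) || any(abs(r2) >= 1)) {
    abort("correlations of magnitude 1 cannot be compared (infinite transform)")
  }
  if (any(n1 <= 3) || any(n2 <= 3)) abort("need n > 3 in both samples")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  tibble::tibble(z = z, p = 2 * pnorm(-abs(z)))
}

#' Benjamini-Hochberg step-up FDR control
#'
#' @param pvalues Vector of p-values in `[0, 1]`.
#' @param alpha FDR level for the rejection flags.
#' @return Tibble `p`, `q`, `reject` in the input order; empty input gives
#'   an empty result.
#' @export
fdr_bh <- function(pvalues, alpha = 0.05) {
  if (length(pvalues) == 0) {
    return(tibble::tibble(p = double(), q = double(), reject = logical()))
  }
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) abort("p-values must be in [0, 1]")
  q <- p.adjust(pvalues, method = "BH")
  tibble::tibble(p = pvalues, q = q, reject = !is.na(q) & q <= alpha)
}

#' Compare regional maturation between two groups
#'
#' For each metric: computes per-region age correlations in each group,
#' restricts to the jointly significant regions (unadjusted `p < alpha`
#' in both), compares the correlations via the Fisher r-to-z statistic,
#' and applies BH-FDR over the regions of each metric separately.
#'
#' @param cohort An aligned `ddi_cohort` with both groups.
#' @param metrics Metrics to analyse (default: every table in the cohort).
#' @param alpha Joint-significance screen level.
#' @return Tidy tibble `metric,region,tissue,r_tdc,p_tdc,r_asd,p_asd,z,
#'   p_cmp,q_cmp`, one row per jointly significant region.
#' @export
compare_maturation <- function(cohort, metrics = names(cohort$tables), alpha = 0.05) {
  stopifnot(inherits(cohort, "ddi_cohort"))
  tdc <- cohort_subset(cohort, "TDC")
  asd <- cohort_subset(cohort, "ASD")
  purrr::map(metrics, function(m) {
    ct <- regional_age_correlation(tdc$tables[[m]], tdc$phenotypes$age)
    ca <- regional_age_correlation(asd$tables[[m]], asd$phenotypes$age)
    joint <- joint_significant_regions(ct, ca, alpha = alpha)
    sel_t <- ct[ct$region %in% joint$region, ]
    sel_a <- ca[match(sel_t$region, ca$region), ]
    if (nrow(sel_t) == 0) return(NULL)
    cmp <- compare_correlations(sel_t$r, sel_t$n, sel_a$r, sel_a$n)
    tibble::tibble(
      metric = m, region = sel_t$region, tissue = sel_t$tissue,
      r_tdc = sel_t$r, p_tdc = sel_t$p,
      r_asd = sel_a$r, p_asd = sel_a$p,
      z = cmp$z, p_cmp = cmp$p,
      q_cmp = fdr_bh(cmp$p, alpha)$q
    )
  }) |> purrr::list_rbind()
}

#' Regional group effect sizes between two metric tables
#'
#' Pooled-SD Cohen's d per region, group A minus group B (so with A the
#' clinical subgroup, positive d means higher values in that subgroup),
#' with a two-sided pooled-variance t-test and BH-FDR over regions.
#' Regions with zero pooled variance are flagged (`d` missing) and left
#' out of the FDR family.
#'
#' @param table_a,table_b `metric_table`s of the same metric and regions,
#'   each with at least 2 participants.
#' @return Tibble `metric,region,tissue,d,p,q`.
#' @export
regional_group_effectsize <- function(table_a, table_b) {
  stopifnot(inherits(table_a, "metric_table"), inherits(table_b, "metric_table"))
  if (!identical(names(table_a), names(table_b))) {
    abort("the two tables must share the same regions")
  }
  va <- table_values(table_a); vb <- table_values(table_b)
  if (nrow(va) < 2 || nrow(vb) < 2) abort("need at least 2 participants per group")
  regions <- table_regions(table_a)
  res <- purrr::map(seq_len(ncol(va)), function(j) {
    a <- va[, j]; b <- vb[, j]
    pooled <- sqrt(((length(a) - 1) * sd(a)^2 + (length(b) - 1) * sd(b)^2) /
                     (length(a) + length(b) - 2))
    if (pooled == 0) return(tibble::tibble(d = NA_real_, p = NA_real_))
    tt <- t.test(a, b, var.equal = TRUE)
    tibble::tibble(d = (mean(a) - mean(b)) / pooled, p = tt$p.value)
  }) |> purrr::list_rbind()
  out <- tibble::tibble(metric = table_metric(table_a),
                        region = regions$name, tissue = regions$tissue,
                        d = res$d, p = res$p, q = NA_real_)
  ok <- !is.na(out$p)
  out$q[ok] <- p.adjust(out$p[ok], method = "BH")
  out
}
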