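#' Raw brain-age gap
#'
#' `brain_age - chronological age`, in years; positive values mean
#' maturationally advanced relative to the normative model.
#'
#' @param brain_age,chron_age Matched numeric vectors, years.
#' @return Numeric vector of per-participant gaps.
#' @export
compute_gap <- function(brain_age, chron_age) {
  if (length(brain_age) != length(chron_age)) abort("length mismatch")
  brain_age - chron_age
}

#' Correct the brain-age gap for regression toward the mean
#'
#' A linear age predictor systematically overestimates young ages and
#' underestimates old ones, so the raw gap correlates with chronological
#' age. The correction regresses the gap on age (ordinary least squares
#' with intercept, fit within the cohort being corrected) and keeps the
#' residuals, which are exactly orthogonal to age.
#'
#' @param raw_gap Raw gaps, years.
#' @param chron_age Chronological ages, years (non-constant, n >= 3).
#' @return Residual gaps, years.
#' @export
bias_correct <- function(raw_gap, chron_age) {
  if (length(raw_gap) != length(chron_age)) abort("length mismatch")
  if (length(raw_gap) < 3) abort("need at least 3 participants")
  if (sd(chron_age) == 0) abort("age is constant; correction undefined")
  unname(resid(lm(raw_gap ~ chron_age)))
}

#' z-normalize the corrected gap into the DDI
#'
#' @param corrected_gap Bias-corrected gaps, years.
#' @return The Developmental Deviation Index: cohort mean 0, SD 1.
#' @export
normalize_ddi <- function(corrected_gap) {
  s <- sd(corrected_gap)
  if (is.na(s) || s == 0) abort("zero variance; DDI undefined")
  (corrected_gap - mean(corrected_gap)) / s
}

#' Stratify a cohort by DDI into developmental subgroups
#'
#' Advanced: `ddi >= advanced_cut` (inclusive); Delayed:
#' `ddi <= delayed_cut` (inclusive); Balanced:
#' `|ddi| < balanced_halfwidth` (strict); everyone else Unassigned. The
#' default cuts (+1 / -1 / 0.2) give the three-subgroup scheme in which
#' the Balanced band is narrow enough to keep its size comparable to the
#' two tails.
#'
#' @param ddi Normalized DDI values.
#' @param advanced_cut,delayed_cut,balanced_halfwidth Cut points; the
#'   Balanced band must not overlap the tails.
#' @return Factor with levels Advanced, Balanced, Delayed, Unassigned.
#' @export
stratify <- function(ddi, advanced_cut = 1, delayed_cut = -1,
                     balanced_halfwidth = 0.2) {
  if (delayed_cut >= advanced_cut) abort("delayed_cut must lie below advanced_cut")
  if (balanced_halfwidth > advanced_cut || balanced_halfwidth > -delayed_cut) {
    abort("balanced band overlaps a tail subgroup")
  }
  out <- rep("Unassigned", length(ddi))
  out[ddi >= advanced_cut] <- "Advanced"
  out[ddi <= delayed_cut] <- "Delayed"
  out[abs(ddi) < balanced_halfwidth] <- "Balanced"
  factor(out, levels = c("Advanced", "Balanced", "Delayed", "Unassigned"))
}

#' Compute the Developmental Deviation Index for a clinical cohort
#'
#' Full scoring chain: predict brain age with the normative model, take
#' the raw gap, regress out chronological age (regression-toward-the-mean
#' correction, fit within the scored cohort by default, or within a
#' reference gap set for sensitivity analysis), z-normalize, stratify.
#'
#' @param model A `normative_model` trained on the normative group.
#' @param features A `feature_matrix` of the cohort to score.
#' @param correction_reference Optional two-column data frame
#'   (`raw_gap`, `age`) from which to estimate the correction line
#'   instead of the scored cohort itself.
#' @param advanced_cut,delayed_cut,balanced_halfwidth Passed to
#'   [stratify()].
#' @return A `ddi_result` tibble: `id`, `brain_age`, `chron_age`,
#'   `raw_gap`, `corrected_gap`, `ddi`, `subgroup`.
#' @export
compute_ddi <- function(model, features, correction_reference = NULL,
                        advanced_cut = 1, delayed_cut = -1,
                        balanced_halfwidth = 0.2) {
  pred <- predict_brain_age(model, features)
  raw_gap <- compute_gap(pred$brain_age, pred$age)
  corrected <- if (is.null(correction_reference)) {
    bias_correct(raw_gap, pred$age)
  } else {
    fit <- lm(raw_gap ~ age, data = correction_reference)
    unname(raw_gap - predict(fit, newdata = data.frame(age = pred$age)))
  }
  ddi <- normalize_ddi(corrected)
  out <- tibble::tibble(
    id = pred$id, brain_age = pred$brain_age, chron_age = pred$age,
    raw_gap = raw_gap, corrected_gap = corrected, ddi = ddi,
    subgroup = stratify(ddi, advanced_cut, delayed_cut, balanced_halfwidth)
  )
  class(out) <- c("ddi_result", class(out))
  out
}

#' Threshold-sweep robustness of the Delayed-vs-Advanced severity gap
#'
#' For each requested per-group size `s`, takes the `s` highest-DDI
#' (Advanced side) and `s` lowest-DDI (Delayed side) participants — i.e.
#' adjusts the DDI threshold to the group size — and reports the
#' common-language effect size `P(severity_Delayed > severity_Advanced)`
#' (ties credited half) with the Mann-Whitney p-value. Ties in DDI at a
#' cut are broken by participant id for determinism.
#'
#' @param ddi Normalized DDI values.
#' @param severity Ordinal severity scores matched to `ddi`.
#' @param sizes Per-group sizes to sweep; each must be at most half the
#'   cohort.
#' @param ids Optional participant ids for deterministic tie-breaks.
#' @return A `sweep_result` tibble: `group_size`, `threshold_advanced`,
#'   `threshold_delayed`, `cles`, `p`.
#' @export
threshold_sweep <- function(ddi, severity, sizes, ids = NULL) {
  if (length(ddi) != length(severity)) abort("length mismatch")
  if (anyNA(severity) || anyNA(ddi)) abort("severity must be available for all swept participants")
  n <- length(ddi)
  if (any(sizes < 1) || any(sizes > n %/% 2)) {
    abort("each group size must be between 1 and half the cohort")
  }
  if (is.null(ids)) ids <- sprintf("p%06d", seq_len(n))
  ord <- order(ddi, ids)  # ascending; ties by id
  out <- purrr::map(sizes, function(s) {
    delayed <- ord[seq_len(s)]
    advanced <- ord[seq(n - s + 1, n)]
    mw <- mann_whitney(severity[delayed], severity[advanced])
    tibble::tibble(
      group_size = s,
      threshold_advanced = min(ddi[advanced]),
      threshold_delayed = max(ddi[delayed]),
      cles = mw$u / (mw$n1 * mw$n2),
      p = mw$p
    )
  }) |> purrr::list_rbind()
  class(out) <- c("sweep_result", class(out))
  out
}
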