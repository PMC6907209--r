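---
title: "Normative brain-age modelling and the Developmental Deviation Index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative brain-age modelling and the Developmental Deviation Index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`ddikit` implements a normative-modelling analysis of brain development.
The core object is a linear age predictor

$$\widehat{\mathrm{age}}_i = w^\top \tilde{x}_i + b,$$

fit exclusively on a typically developing cohort (TDC), where $\tilde{x}_i$
is the standardized vector of regional brain metrics for participant $i$:
cortical volume, surface area and thickness over 68 cortical regions, and
FA and ADC over 176 regions spanning white matter, cortical and subcortical
grey matter (556 features for the combined model). The prediction
$\widehat{\mathrm{age}}_i$ is the participant's *brain age*; applying the
TDC-trained model to a clinical cohort scores every individual against
normative development.

The per-participant deviation is processed in three steps:

1. **Raw gap** $g_i = \widehat{\mathrm{age}}_i - \mathrm{age}_i$ (years).
   Positive means maturationally advanced.
2. **Regression-toward-the-mean correction.** Any regularized linear
   predictor compresses predictions toward the training mean, so $g_i$ is
   negatively correlated with age even for perfectly normative subjects.
   We regress $g$ on age (OLS with intercept, within the cohort being
   scored) and keep the residuals, which are exactly orthogonal to age.
3. **Normalization.** The residuals are z-scored within the cohort, giving
   the Developmental Deviation Index (DDI): mean 0, SD 1, unitless.

The clinical cohort is stratified by DDI into **Advanced** ($\ge +1$,
inclusive), **Delayed** ($\le -1$, inclusive) and **Balanced**
($|\mathrm{DDI}| < 0.2$, strict); anyone else is Unassigned. The narrow
Balanced band keeps that subgroup's size comparable to the two tails. The
DDI–severity relationship is quantified with Spearman correlation (severity
is ordinal), Fisher-transform CIs with $\mathrm{SE} = 1/\sqrt{n-3}$,
common-language effect sizes, and a proportional-odds robustness model
`Severity ~ DDI + Motion + IQ`.

### Backends

* `linear_svr` (default): epsilon-insensitive support vector regression
  with a linear kernel and the reference defaults $C = 1$,
  $\varepsilon = 0.1$. A linear kernel keeps the per-feature weights
  interpretable as regional contributions.
* `l1_linear`: lasso, with the penalty chosen by internal 10-fold
  cross-validation on deterministic folds.
* `bayesian_linear`: conjugate Gaussian regression whose prior and noise
  precisions are set by evidence maximisation (MacKay fixed-point
  updates), computed through the SVD of the design so it is stable at
  $p \gg n$.

Features are standardized by the training mean and SD before fitting.
This is a modelling choice the analysis depends on: the five metrics live
on incommensurate scales (mm^3 vs unitless FA), and without
standardization the weight magnitudes could not be compared across
metrics. The standardization parameters are frozen at fit time and, during
cross-validation, recomputed from each training fold only — the held-out
fold never contributes, which the suite verifies by checking that
accuracy does not inflate when ages are independent noise.

### Cross-validation protocol

Accuracy is assessed by repeated k-fold cross-validation: each repeat
shuffles the participants, splits them into $k = 10$ folds, pools the
out-of-fold predictions and records a single Pearson r against
chronological age. The summary is the mean of the per-repeat r values and
a 95% CI from their 2.5th/97.5th percentiles — a deliberately
assumption-free reading of "the distribution of r values". The full
protocol uses 1000 repeats; the mean is stable to ±0.01 beyond a few
dozen repeats on fixed data, so the default here is 50 (tests use 3–20)
and `repeats` is exposed for exact replication. No feature selection is
performed at any point.

A technical note on the null behaviour of this protocol: for a fixed
dataset, the repeat-mean converges to a dataset-conditional value, which
under independence of features and age is only *on average* zero across
datasets. Strongly shrunk backends (the Bayesian ridge) show the classic
negative bias — predictions collapse toward the training-fold mean, which
anticorrelates with the held-out ages — while the SVR's epsilon tube keeps
it closer to zero. The tests therefore average the null check over
several data draws.

## The statistical battery

* Per-region Pearson age correlations, with p-values from the exact t
  reference distribution on $n-2$ df; two-sided throughout (the
  conservative default where sidedness is not forced by the question).
* TDC-vs-clinical comparison of correlations via the Fisher r-to-z
  statistic $z = (\mathrm{atanh}\,r_1 - \mathrm{atanh}\,r_2)\big/
  \sqrt{1/(n_1-3) + 1/(n_2-3)}$, restricted to regions whose age
  correlation is significant (unadjusted $p < 0.05$) in *both* groups —
  a comparison of slopes is only meaningful where an age effect exists.
* Benjamini–Hochberg FDR, applied per metric (the family is the regions
  of one metric; comparisons are not pooled across metrics).
* Cohen's d with $(n-1)$-weighted pooled SD; the common-language effect
  size $\mathrm{CLES} = (\#\{a > b\} + \tfrac12\#\{a = b\})/(n_1 n_2)$,
  identical to Mann-Whitney $U/(n_1 n_2)$ under the wins-plus-half-ties
  convention (the convention is pinned down by the identity
  $U/(n_1 n_2) = \mathrm{CLES}$); U p-values exact when tie-free and
  $n_1 n_2 \le 400$, otherwise the tie-corrected normal approximation.
* Pearson chi-square on the 2x2 sex-by-group table *without* continuity
  correction (the uncorrected statistic is the one that reproduces the
  worked demographic example).
* Proportional-odds cumulative-logit model via `MASS::polr` with Wald
  p-values; logit link, the standard choice where only "ordinal
  regression" is specified.

## What the synthetic cohort emulates

`generate_cohort()` draws, per region $r$ and metric $m$,

$$x_{irm} = a_{rm} + s_{rm}\,(\mathrm{age}_i + \delta_i) + \epsilon_{irm},$$

with slopes $s_{rm}$ sampled per tissue class so that FA rises and ADC
falls with age in white matter and subcortical grey matter, thickness and
volume decline, and surface area is essentially flat. The per-subject
deviation $\delta_i \sim N(0, \sigma_\delta^2)$ (clinical group only,
default $\sigma_\delta = 1.5$ years) enters as an *effective-age shift
along each region's own slope*, not as additive noise: the DDI is defined
in age units, so this makes the ground truth directly comparable to the
corrected gap. Severity is a latent $-\beta\,\delta + N(0, \sigma_s^2)$
discretised into deciles of its *design* distribution, so a zero link
gives exactly uniform severities and the scale 1–10 stays fully
populated; $\beta$ is derived in closed form from the target rank
correlation through the bivariate-normal identity
$\rho_S = (6/\pi)\arcsin(\rho/2)$ (default target $-0.3$; Monte-Carlo
checks show the realized calibration is exact to ~0.002, with the 10-bin
discretisation attenuating it only marginally). One master seed expands
into independent substreams for ages/phenotypes, slopes, noise,
deviations and severity, so changing one component leaves the others
bit-identical.

Default sizes (220 TDC / 247 clinical, ages uniform on 6–25, male
fractions 161/220 and 203/247) mirror a cross-sectional developmental
sample. Residual SDs were set so that single-metric cross-validated
accuracies fall in a realistic band — regional FA correlations with age
around 0.8, volume weaker, surface area weakest (the area slope SD of
0.5 mm²/yr keeps the area metric nearly flat, consistent with its design
role as the least age-informative metric).

What the generator deliberately does **not** emulate: between-region
covariance beyond the shared age factor, scanner or site effects,
nonlinear maturation curves, and missing-data patterns. Passing tests on
these cohorts therefore demonstrate the *pipeline's* correctness
(parameter recovery, bias-correction behaviour, calibration of the
statistics under the null), not that real developmental data satisfy the
linear model.

## Numerical and design choices

* **Correction reference.** The bias-correction regression is fit within
  the cohort being corrected (the clinical sample), matching the scoring
  setting; `compute_ddi(correction_reference = ...)` lets a sensitivity
  analysis fit the line on normative out-of-sample gaps instead. On the
  synthetic cohorts the two agree closely.
* **Boundaries.** Subgroup cuts are inclusive at ±1 and strict at ±0.2 —
  taken literally from the stratification definition. Ties in the
  threshold sweep are broken by participant id for determinism.
* **Degenerate inputs.** Constant features are standardized to zero with
  a warning; zero-variance regions are flagged and excluded from the FDR
  family; correlations of magnitude 1 refuse the Fisher transform; a
  constant-age cohort refuses bias correction.
* **Determinism.** Every random draw in `run_full_analysis()` traces to
  the single config seed; reruns are byte-identical, and the report
  records the seed, a config hash and the package version.
* **Problem sizes.** The suite runs its heavy property checks at
  n_tdc = 220 / n_asd = 176 (100 seeds for sign recovery) and scales the
  null-calibration replicates to 100/80 participants with the closed-form
  Bayesian backend — sizes chosen to give stable Monte-Carlo estimates in
  minutes on a single core.

## Known limitations

* The linear predictor is the point: nonlinear kernels, deep models and
  hyperparameter search are out of scope, as is any nonlinear
  (quadratic/cubic) maturation fit.
* The Bayesian backend provides a posterior-mean predictor only; the
  uncertainty-weighted scoring variant that would propagate predictive
  variance into the DDI is not implemented.
* The Fisher-transform CI is applied to Spearman coefficients exactly as
  to Pearson's r — the single stated recipe — although the Spearman
  sampling variance is slightly larger; at the cohort sizes involved the
  difference is well inside the CI rounding.
* At very small n the Fisher CI explodes for moderate correlations but
  compresses again as $|r| \to 1$ (the back-transform saturates); CIs at
  $n \lesssim 10$ should not be interpreted.

## A worked example

```{r, eval = FALSE}
library(ddikit)

sim <- sim_config(n_tdc = 220, n_asd = 176, seed = 1)
g <- generate_cohort(sim)

fa_tdc <- assemble_features(g$cohort, "fa", group = "TDC")
model <- fit_normative(fa_tdc)                    # linear SVR on TDC only
repeated_cv(fa_tdc, repeats = 20, seed = 1)       # 10-fold CV accuracy

ddi <- compute_ddi(model, assemble_features(g$cohort, "fa", group = "ASD"))
sev <- g$cohort$phenotypes$ados_css[match(ddi$id, g$cohort$phenotypes$id)]
spearman_with_ci(ddi$ddi, sev)                    # the DDI-severity link
table(ddi$subgroup)

autoplot(ddi)
plot_severity_by_subgroup(ddi, sev)
```

The one-call orchestration, `run_full_analysis(run_config(...))`, runs
the full sequence — maturation comparison, the six normative models,
external testing, DDI, subgroup hierarchy, threshold sweep, sex checks
and the ordinal model — and writes tidy CSVs plus `report.json` /
`report.md` when an output directory is given.
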