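#' Simulation configuration for a synthetic developmental cohort
#'
#' Encodes the statistical structure the analysis assumes: approximately
#' linear age effects whose sign and magnitude vary by region and tissue
#' (FA rising / ADC falling with age in white matter and subcortical grey
#' matter; cortical thickness and volume falling; surface area close to
#' flat), a per-subject developmental deviation `delta` (in years) for the
#' clinical group that shifts every region along its own maturation slope,
#' and an ordinal 1-10 severity score negatively linked to `delta`.
#'
#' Default cohort sizes and sex ratios follow a cross-sectional
#' developmental sample of 220 typically developing children (TDC) and 247
#' autistic children and young adults aged 6-25 years; `deviation_sd`
#' defaults to 1.5 years and the severity link is calibrated so the design
#' Spearman correlation between `delta` and severity is -0.3.
#'
#' @param n_tdc,n_asd Group sizes.
#' @param age_range Chronological age range in years, sampled uniformly.
#' @param n_anat_regions Regions per anatomical metric (68: a bilateral
#'   34-regions-per-hemisphere cortical atlas).
#' @param n_diff_regions Regions per diffusion metric (176, spanning white
#'   matter, cortical and subcortical grey matter).
#' @param deviation_sd SD, in years, of the per-subject deviation `delta`
#'   added to the effective age of ASD participants (0 = null cohort).
#' @param target_spearman Design Spearman correlation between `delta` and
#'   severity (the link coefficient is derived from it; see
#'   [severity_link_for_spearman()]). Ignored if `severity_link` is given.
#' @param severity_link Latent-scale coefficient `beta >= 0` multiplying
#'   `-delta`; overrides `target_spearman` when non-`NULL`.
#' @param severity_noise_sd SD of the latent severity noise.
#' @param residual_sd Named per-metric residual noise SD, in each metric's
#'   own units (mm^3, mm^2, mm, unitless FA, mm^2/s). Scale them jointly
#'   toward 0 for a noiseless cohort.
#' @param noise_scale Convenience multiplier applied to all residual SDs.
#' @param sex_ratio_tdc,sex_ratio_asd Probability of male sex per group.
#' @param seed Integer master seed; expanded into independent substreams
#'   for ages/sex, slopes, noise, deviations and severity.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_tdc = 220, n_asd = 247,
                       age_range = c(6, 25),
                       n_anat_regions = 68, n_diff_regions = 176,
                       deviation_sd = 1.5,
                       target_spearman = -0.3,
                       severity_link = NULL,
                       severity_noise_sd = 1,
                       residual_sd = c(volume = 250, area = 120, thickness = 0.09,
                                       fa = 0.02, adc = 4e-5),
                       noise_scale = 1,
                       sex_ratio_tdc = 161 / 220, sex_ratio_asd = 203 / 247,
                       seed = 1) {
  stopifnot(age_range[1] < age_range[2], deviation_sd >= 0,
            severity_noise_sd >= 0, noise_scale >= 0,
            n_anat_regions %% 2 == 0, n_diff_regions %% 2 == 0)
  if (is.null(severity_link)) {
    severity_link <- if (deviation_sd > 0) {
      severity_link_for_spearman(abs(target_spearman), deviation_sd, severity_noise_sd)
    } else 0
  }
  stopifnot(severity_link >= 0)
  residual_sd <- residual_sd[METRICS] * noise_scale
  structure(list(
    n_tdc = n_tdc, n_asd = n_asd, age_range = age_range,
    n_anat_regions = n_anat_regions, n_diff_regions = n_diff_regions,
    deviation_sd = deviation_sd, severity_link = severity_link,
    severity_noise_sd = severity_noise_sd,
    residual_sd = residual_sd,
    sex_ratio_tdc = sex_ratio_tdc, sex_ratio_asd = sex_ratio_asd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Severity-link coefficient for a target design Spearman correlation
#'
#' The latent severity is `-beta * delta + eps` with Gaussian `delta` and
#' `eps`, so the latent Pearson correlation with `delta` is
#' `rho = -beta * sd_delta / sqrt(beta^2 sd_delta^2 + sd_eps^2)`. For a
#' bivariate normal pair the Spearman correlation is
#' `(6 / pi) * asin(rho / 2)`; inverting both relations gives the `beta`
#' whose design rank correlation matches the target (the subsequent
#' 10-bin discretisation attenuates it only marginally).
#'
#' @param target_spearman Desired |Spearman| between deviation and severity.
#' @param deviation_sd SD of `delta` (years).
#' @param severity_noise_sd SD of the latent noise.
#' @return The non-negative link coefficient `beta`.
#' @export
severity_link_for_spearman <- function(target_spearman, deviation_sd, severity_noise_sd) {
  stopifnot(target_spearman >= 0, target_spearman < 1, deviation_sd > 0)
  rho <- 2 * sin(pi * target_spearman / 6)
  if (severity_noise_sd == 0) return(1)  # any positive beta gives a deterministic link
  rho / sqrt(1 - rho^2) * severity_noise_sd / deviation_sd
}

# per metric x tissue: mean and sd of the linear age slope, and the
# intercept distribution, in each metric's own units
slope_spec <- function() {
  tibble::tribble(
    ~metric,     ~tissue,          ~slope_mean, ~slope_sd, ~int_mean, ~int_sd,
    "fa",        "wm",                  0.0055,    0.0015,      0.42,    0.05,
    "fa",        "subcortical_gm",      0.0040,    0.0012,      0.28,    0.04,
    "fa",        "cortical_gm",         0.0012,    0.0010,      0.22,    0.03,
    "fa",        "other",               0.0005,    0.0010,      0.30,    0.05,
    "adc",       "wm",                 -1.1e-5,     3.0e-6,    8.5e-4,   4e-5,
    "adc",       "subcortical_gm",     -0.9e-5,     2.5e-6,    8.0e-4,   4e-5,
    "adc",       "cortical_gm",        -0.6e-5,     2.5e-6,    9.0e-4,   4e-5,
    "adc",       "other",              -0.2e-5,     2.0e-6,    9.0e-4,   5e-5,
    "thickness", "cortical_gm",        -0.020,      0.006,       2.9,     0.2,
    "volume",    "cortical_gm",          -40,         15,       9000,    2500,
    "area",      "cortical_gm",            0,        0.5,       2600,     700
  )
}

diffusion_region_layout <- function(n_regions) {
  # per hemisphere: ~45% wm, ~39% cortical gm, ~14% subcortical gm, rest other
  half <- n_regions %/% 2
  n_wm <- round(0.45 * half); n_cgm <- round(0.39 * half)
  n_sgm <- round(0.14 * half); n_oth <- half - n_wm - n_cgm - n_sgm
  tissue <- rep(c("wm", "cortical_gm", "subcortical_gm", "other"),
                c(n_wm, n_cgm, n_sgm, n_oth))
  tibble::tibble(
    name = c(paste0("lh_diff_", sprintf("%02d", seq_len(half))),
             paste0("rh_diff_", sprintf("%02d", seq_len(half)))),
    hemisphere = rep(c("left", "right"), each = half),
    tissue = rep(tissue, 2)
  )
}

anatomical_region_layout <- function(n_regions) {
  half <- n_regions %/% 2
  tibble::tibble(
    name = c(paste0("lh_ctx_", sprintf("%02d", seq_len(half))),
             paste0("rh_ctx_", sprintf("%02d", seq_len(half)))),
    hemisphere = rep(c("left", "right"), each = half),
    tissue = "cortical_gm"
  )
}

#' Generate a synthetic TDC + ASD cohort with ground truth
#'
#' Each regional value is `intercept + slope * effective_age + noise`,
#' where `effective_age = age` for TDC and `age + delta` for ASD with
#' `delta ~ N(0, deviation_sd^2)`: the deviation is an effective-age shift
#' along each region's own maturation slope, so the ground truth is
#' directly comparable, in years, to the brain-age gap the pipeline
#' estimates. Severity (ADOS-CSS-like, ordinal 1-10) is generated for all
#' ASD participants from `delta` via [generate_severity()]. The master
#' seed is expanded into independent substreams (ages/sex/phenotype,
#' slopes, noise, deviations, severity) so changing one component leaves
#' the others untouched.
#'
#' @param config A [sim_config()].
#' @return A list with elements `cohort` (a `ddi_cohort` with all five
#'   metric tables) and `truth` (list: `delta` tibble `id,delta`,
#'   `slopes` tibble of the true per-region age coefficients).
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sub <- sample.int(.Machine$integer.max - 1L, 5L)

  n <- config$n_tdc + config$n_asd
  ids <- c(sprintf("tdc_%03d", seq_len(config$n_tdc)),
           sprintf("asd_%03d", seq_len(config$n_asd)))
  group <- rep(c("TDC", "ASD"), c(config$n_tdc, config$n_asd))

  # substream 1: ages, sex, iq, motion
  set.seed(sub[1])
  age <- runif(n, config$age_range[1], config$age_range[2])
  male <- rbinom(n, 1, ifelse(group == "TDC", config$sex_ratio_tdc, config$sex_ratio_asd))
  iq_total <- round(rnorm(n, ifelse(group == "TDC", 103, 96), 16))
  iq_verbal <- round(iq_total + rnorm(n, 0, 7))
  iq_nonverbal <- round(iq_total + rnorm(n, 0, 7))
  motion <- round(abs(rnorm(n, 0.35, 0.25)) + 0.05, 4)

  # substream 2: region layouts and true slopes/intercepts
  set.seed(sub[2])
  spec <- slope_spec()
  layouts <- c(
    purrr::map(setNames(ANAT_METRICS, ANAT_METRICS),
               ~ anatomical_region_layout(config$n_anat_regions)),
    purrr::map(setNames(DIFF_METRICS, DIFF_METRICS),
               ~ diffusion_region_layout(config$n_diff_regions))
  )
  slopes <- purrr::imap(layouts, function(layout, metric) {
    par <- dplyr::left_join(
      dplyr::mutate(layout, metric = metric), spec,
      by = c("metric", "tissue")
    )
    dplyr::mutate(par,
                  slope = rnorm(dplyr::n(), .data$slope_mean, .data$slope_sd),
                  intercept = rnorm(dplyr::n(), .data$int_mean, .data$int_sd))
  })

  # substream 4 (before noise so the noise stream is last): deviations
  set.seed(sub[4])
  delta <- rep(0, n)
  delta[group == "ASD"] <- rnorm(config$n_asd, 0, config$deviation_sd)
  eff_age <- age + delta

  # substream 3: measurement noise
  set.seed(sub[3])
  tables <- purrr::imap(slopes, function(sl, metric) {
    p <- nrow(sl)
    vals <- matrix(sl$intercept, n, p, byrow = TRUE) +
      outer(eff_age, sl$slope) +
      matrix(rnorm(n * p, 0, config$residual_sd[[metric]]), n, p)
    if (metric == "fa") vals <- pmin(pmax(vals, 0), 1)
    df <- tibble::as_tibble(as.data.frame(vals, col.names = sl$name))
    names(df) <- sl$name
    metric_table(dplyr::bind_cols(tibble::tibble(id = ids), df),
                 metric = metric,
                 regions = region_info(sl$name, sl$hemisphere, sl$tissue))
  })

  # substream 5: severity for the clinical group
  ados <- rep(NA_real_, n)
  ados[group == "ASD"] <- generate_severity(
    delta[group == "ASD"],
    severity_link = config$severity_link,
    severity_noise_sd = config$severity_noise_sd,
    deviation_sd = config$deviation_sd,
    seed = sub[5]
  )

  phenotypes <- tibble::tibble(
    id = ids, group = group, age = age,
    sex = ifelse(male == 1, "M", "F"),
    iq_verbal = iq_verbal, iq_nonverbal = iq_nonverbal, iq_total = iq_total,
    ados_css = ados, motion = motion
  )
  cohort <- align_cohort(phenotypes, tables)
  truth <- list(
    delta = tibble::tibble(id = ids[group == "ASD"], delta = delta[group == "ASD"]),
    slopes = purrr::imap(slopes, ~ dplyr::select(.x, "metric", region = "name",
                                                 "tissue", "slope", "intercept")) |>
      purrr::list_rbind()
  )
  list(cohort = cohort, truth = truth)
}

#' Generate ordinal severity scores from developmental deviations
#'
#' A latent score `-severity_link * delta + N(0, severity_noise_sd^2)` is
#' discretised into the ordinal 1-10 scale by the fixed decile edges of
#' its *design* distribution (the normal implied by `deviation_sd`,
#' `severity_link` and `severity_noise_sd`), not by empirical quantiles:
#' with a zero link the marginal severity distribution is uniform over the
#' ten levels, and a larger deviation (more advanced maturation) gives
#' stochastically lower severity.
#'
#' @param delta Per-subject developmental deviations, years.
#' @param severity_link Non-negative latent coefficient on `-delta`.
#' @param severity_noise_sd Latent noise SD.
#' @param deviation_sd Design SD of `delta`, used to fix the bin edges;
#'   defaults to the sample SD of `delta`.
#' @param seed Integer seed for the latent noise.
#' @return Integer severity scores in 1..10.
#' @export
generate_severity <- function(delta, severity_link, severity_noise_sd,
                              deviation_sd = sd(delta), seed = 1) {
  stopifnot(severity_link >= 0, severity_noise_sd >= 0)
  set.seed(seed)
  latent <- -severity_link * delta + rnorm(length(delta), 0, severity_noise_sd)
  if (is.na(deviation_sd)) deviation_sd <- 0
  design_sd <- sqrt(severity_link^2 * deviation_sd^2 + severity_noise_sd^2)
  if (design_sd == 0) return(rep(5L, length(delta)))
  edges <- qnorm(seq(0.1, 0.9, by = 0.1), 0, design_sd)
  as.integer(findInterval(latent, edges) + 1L)
}

#' Write a simulated cohort (and its ground truth) to CSV files
#'
#' Emits one CSV per metric table, the phenotype CSV, a region metadata
#' CSV per modality and, when ground truth is supplied, `truth_delta.csv`
#' (`id,delta`).
#'
#' @param cohort A `ddi_cohort`.
#' @param dir Output directory (created if absent).
#' @param truth Optional ground-truth list from [generate_cohort()].
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir, truth = NULL) {
  stopifnot(inherits(cohort, "ddi_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_phenotypes(cohort$phenotypes, file.path(dir, "phenotypes.csv"))
  purrr::iwalk(cohort$tables, function(tab, metric) {
    write_metric_table(tab, file.path(dir, paste0("metric_", metric, ".csv")))
    readr::write_csv(table_regions(tab), file.path(dir, paste0("regions_", metric, ".csv")))
  })
  if (!is.null(truth)) {
    readr::write_csv(truth$delta, file.path(dir, "truth_delta.csv"))
    readr::write_csv(truth$slopes, file.path(dir, "truth_slopes.csv"))
  }
  invisible(dir)
}
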