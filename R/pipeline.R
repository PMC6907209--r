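#' Serialize a normative model to JSON
#'
#' Stores backend, feature names, frozen standardization parameters,
#' weights, intercept and training metadata; [read_normative_model()]
#' restores an equivalent model.
#'
#' @param model A `normative_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_normative_model <- function(model, path) {
  stopifnot(inherits(model, "normative_model"))
  jsonlite::write_json(
    list(backend = model$backend, feature_names = model$feature_names,
         center = unname(model$center), scale = unname(model$scale),
         weights = model$weights, intercept = model$intercept,
         train_ids = model$train_ids, n_train = model$n_train,
         training_r = model$training_r),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a normative model from JSON
#' @param path JSON path written by [write_normative_model()].
#' @return A `normative_model`.
#' @export
read_normative_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    backend = obj$backend, feature_names = obj$feature_names,
    center = setNames(obj$center, obj$feature_names),
    scale = setNames(obj$scale, obj$feature_names),
    weights = obj$weights, intercept = obj$intercept,
    train_ids = obj$train_ids, n_train = obj$n_train,
    training_r = obj$training_r
  ), class = "normative_model")
}

#' Configuration for a full analysis run
#'
#' @param simulation A [sim_config()] describing the synthetic cohort, or
#'   `NULL` when `paths` supplies real tables.
#' @param paths Optional list with `phenotypes` (CSV path), `metrics`
#'   (named list metric -> CSV path) and optionally `regions` (named list
#'   metric -> region metadata CSV).
#' @param metric_sets Feature sets to model; default the five single
#'   metrics plus the combined five-metric set.
#' @param backend Model family, see [fit_normative()].
#' @param k,repeats,seed Cross-validation folds, repeats, and the seed
#'   driving every random draw of the run.
#' @param subgroup_metric Which model's DDI feeds the subgroup,
#'   threshold-sweep, sex and ordinal analyses (default `"fa"`).
#' @param advanced_cut,delayed_cut,balanced_halfwidth Stratification cuts.
#' @param sweep_sizes Per-group sizes for [threshold_sweep()].
#' @param output_dir Where to write the report bundle (`NULL`: in-memory
#'   results only).
#' @return A `run_config` list.
#' @export
run_config <- function(simulation = sim_config(),
                       paths = NULL,
                       metric_sets = c(as.list(METRICS), list(METRICS)),
                       backend = "linear_svr",
                       k = 10, repeats = 50, seed = 1,
                       subgroup_metric = "fa",
                       advanced_cut = 1, delayed_cut = -1, balanced_halfwidth = 0.2,
                       sweep_sizes = c(10, 15, 19, 23, 27),
                       output_dir = NULL) {
  if (is.null(simulation) && is.null(paths)) {
    abort("either a simulation config or input paths must be given")
  }
  if (repeats < 2) abort("repeats must be >= 2")
  if (k < 2) abort("k must be >= 2")
  structure(list(simulation = simulation, paths = paths,
                 metric_sets = metric_sets, backend = backend,
                 k = k, repeats = repeats, seed = as.integer(seed),
                 subgroup_metric = subgroup_metric,
                 advanced_cut = advanced_cut, delayed_cut = delayed_cut,
                 balanced_halfwidth = balanced_halfwidth,
                 sweep_sizes = sweep_sizes, output_dir = output_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; a `simulation`
#' mapping is passed to [sim_config()], a `paths` mapping to the readers.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$simulation)) do.call(sim_config, y$simulation) else NULL
  args <- y[setdiff(names(y), "simulation")]
  args$simulation <- sim
  if (!is.null(args$age_range)) args$age_range <- unlist(args$age_range)
  if (!is.null(args$sweep_sizes)) args$sweep_sizes <- unlist(args$sweep_sizes)
  do.call(run_config, args)
}

load_cohort_from_paths <- function(paths) {
  phenotypes <- read_phenotypes(paths$phenotypes)
  tables <- purrr::imap(paths$metrics, function(p, m) {
    read_metric_table(p, metric = m, region_metadata = paths$regions[[m]])
  })
  list(phenotypes = phenotypes, tables = tables)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the full normative-deviation analysis
#'
#' Orchestrates the whole sequence on a synthetic or user-supplied cohort:
#' regional maturation comparison (TDC vs ASD), one normative model per
#' metric set (trained on TDC, evaluated by repeated k-fold CV and by
#' external test on ASD), the bias-corrected DDI per model, the
#' DDI-severity Spearman correlation with BH correction across the metric
#' sets, subgroup stratification with hierarchy tests and the
#' threshold-sweep robustness check, sex-difference checks (DDI by sex and
#' a male-only refit of the severity correlation), and the
#' proportional-odds robustness model `Severity ~ DDI + Motion + IQ`.
#'
#' With an `output_dir` the bundle is also written out as tidy CSVs,
#' `report.json` and a `report.md` summary; reruns with the same config
#' are byte-identical. Every random draw traces to `config$seed`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with elements `maturation`, `models`,
#'   `severity_models`, `ddi`, `subgroups`, `sweep`, `sex`, `ordinal`,
#'   `meta`.
#' @export
run_full_analysis <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))

  raw <- run_stage("load_cohort", {
    if (!is.null(config$paths)) {
      c(load_cohort_from_paths(config$paths), list(truth = NULL))
    } else {
      sim <- config$simulation
      sim$seed <- config$seed
      g <- generate_cohort(sim)
      list(phenotypes = g$cohort$phenotypes, tables = g$cohort$tables,
           truth = g$truth)
    }
  })

  maturation <- run_stage("maturation", {
    purrr::map(names(raw$tables), function(m) {
      co <- align_cohort(raw$phenotypes, raw$tables[m])
      compare_maturation(co, metrics = m)
    }) |> purrr::list_rbind()
  })

  set_label <- function(ms) if (length(ms) > 1) "combined" else ms
  models <- run_stage("normative_models", {
    purrr::map(config$metric_sets, function(ms) {
      co <- align_cohort(raw$phenotypes, raw$tables, required_metrics = ms)
      feats_tdc <- assemble_features(co, metrics = ms, group = "TDC")
      model <- suppressWarnings(fit_normative(feats_tdc, backend = config$backend))
      cv <- suppressWarnings(repeated_cv(feats_tdc, backend = config$backend,
                                         k = config$k, repeats = config$repeats,
                                         seed = config$seed))
      feats_asd <- assemble_features(co, metrics = ms, group = "ASD")
      test <- external_test_accuracy(model, feats_asd)
      # DDI within the ASD participants who also have a severity score
      ph_asd <- co$phenotypes[co$phenotypes$group == "ASD", ]
      sev_ids <- ph_asd$id[!is.na(ph_asd$ados_css)]
      sub <- subset_features(feats_asd, sev_ids)
      ddi <- if (length(sev_ids) >= 3) {
        compute_ddi(model, sub,
                    advanced_cut = config$advanced_cut,
                    delayed_cut = config$delayed_cut,
                    balanced_halfwidth = config$balanced_halfwidth)
      } else NULL
      severity <- ph_asd$ados_css[match(sev_ids, ph_asd$id)]
      sev_cor <- if (!is.null(ddi)) spearman_with_ci(ddi$ddi, severity) else NULL
      list(set = set_label(ms), metrics = ms, model = model, cv = cv,
           test = test, ddi = ddi, severity = severity, sev_cor = sev_cor)
    })
  })

  severity_models <- run_stage("severity_correlations", {
    tab <- purrr::map(models, function(m) {
      dplyr::mutate(m$sev_cor, set = m$set, .before = 1)
    }) |> purrr::list_rbind()
    dplyr::mutate(tab, q = fdr_bh(.data$p)$q)
  })

  key <- purrr::detect(models, ~ .x$set == config$subgroup_metric)
  if (is.null(key)) abort("subgroup_metric does not name a fitted metric set")
  ddi <- key$ddi
  severity <- key$severity

  subgroups <- run_stage("subgroup_hierarchy", {
    by_grp <- split(severity, ddi$subgroup)[c("Advanced", "Balanced", "Delayed")]
    kw <- kruskal_wallis(by_grp)
    dva <- effect_size_report(by_grp$Delayed, by_grp$Advanced)
    summary_tbl <- dplyr::mutate(tibble::as_tibble(ddi), severity = severity) |>
      dplyr::filter(.data$subgroup != "Unassigned") |>
      dplyr::group_by(.data$subgroup) |>
      dplyr::summarise(n = dplyr::n(),
                       mean_severity = mean(.data$severity),
                       sd_severity = sd(.data$severity),
                       mean_age = mean(.data$chron_age), .groups = "drop")
    list(summary = summary_tbl, kruskal = kw, delayed_vs_advanced = dva)
  })

  sweep <- run_stage("threshold_sweep", {
    sizes <- config$sweep_sizes[config$sweep_sizes <= nrow(ddi) %/% 2]
    threshold_sweep(ddi$ddi, severity, sizes = sizes, ids = ddi$id)
  })

  sex <- run_stage("sex_differences", {
    ph <- raw$phenotypes
    counts <- table(ph$group, ph$sex)[c("TDC", "ASD"), c("M", "F")]
    ratio <- chi2_2x2(counts)
    sex_of <- ph$sex[match(ddi$id, ph$id)]
    ddi_by_sex <- effect_size_report(ddi$ddi[sex_of == "M"], ddi$ddi[sex_of == "F"])
    male_rerun <- male_only_severity(raw, key$metrics, config)
    list(ratio = ratio, ddi_by_sex = ddi_by_sex, male_only = male_rerun)
  })

  ordinal <- run_stage("ordinal_robustness", {
    ph <- raw$phenotypes
    at <- match(ddi$id, ph$id)
    covs <- tibble::tibble(ddi = ddi$ddi, motion = ph$motion[at],
                           iq_total = ph$iq_total[at])
    ordinal_fit(severity, covs)
  })

  meta <- list(seed = config$seed, backend = config$backend,
               k = config$k, repeats = config$repeats,
               config_hash = rlang::hash(unclass(config)[setdiff(names(config), "output_dir")]),
               version = as.character(utils::packageVersion("ddikit")))

  bundle <- list(maturation = maturation, models = models,
                 severity_models = severity_models, ddi = ddi,
                 subgroups = subgroups, sweep = sweep, sex = sex,
                 ordinal = ordinal, truth = raw$truth, meta = meta)
  if (!is.null(config$output_dir)) {
    run_stage("write_report", write_report_bundle(bundle, config))
  }
  invisible(bundle)
}

subset_features <- function(features, ids) {
  keep <- match(ids, features$ids)
  structure(list(ids = features$ids[keep],
                 feature_names = features$feature_names,
                 x = features$x[keep, , drop = FALSE],
                 ages = features$ages[keep],
                 metrics = features$metrics),
            class = "feature_matrix")
}

# male-only sensitivity rerun: retrain the key model on male TDC, rescore
# male ASD, recompute the severity correlation
male_only_severity <- function(raw, metrics, config) {
  ph <- raw$phenotypes[raw$phenotypes$sex == "M", ]
  co <- tryCatch(align_cohort(ph, raw$tables, required_metrics = metrics),
                 error = function(e) NULL)
  if (is.null(co) || sum(co$phenotypes$group == "TDC") < 10) return(NULL)
  feats_tdc <- assemble_features(co, metrics = metrics, group = "TDC")
  model <- suppressWarnings(fit_normative(feats_tdc, backend = config$backend))
  ph_asd <- co$phenotypes[co$phenotypes$group == "ASD", ]
  sev_ids <- ph_asd$id[!is.na(ph_asd$ados_css)]
  if (length(sev_ids) < 5) return(NULL)
  feats_asd <- assemble_features(co, metrics = metrics, group = "ASD")
  ddi <- compute_ddi(model, subset_features(feats_asd, sev_ids))
  spearman_with_ci(ddi$ddi, ph_asd$ados_css[match(sev_ids, ph_asd$id)])
}

write_report_bundle <- function(bundle, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)
  readr::write_csv(bundle$maturation, out("maturation.csv"))
  accuracy <- purrr::map(bundle$models, function(m) {
    tibble::tibble(set = m$set, n_features = length(m$model$weights),
                   n_train = m$model$n_train,
                   cv_mean_r = m$cv$mean_r, cv_ci_low = m$cv$ci_low,
                   cv_ci_high = m$cv$ci_high,
                   test_r = m$test$r, test_n = m$test$n,
                   test_ci_low = m$test$ci_low, test_ci_high = m$test$ci_high)
  }) |> purrr::list_rbind()
  readr::write_csv(accuracy, out("accuracy.csv"))
  readr::write_csv(bundle$severity_models, out("severity_models.csv"))
  readr::write_csv(tibble::as_tibble(bundle$ddi), out("ddi.csv"))
  readr::write_csv(tibble::as_tibble(bundle$sweep), out("sweep.csv"))
  for (m in bundle$models) {
    if (m$set %in% c("combined", config$subgroup_metric)) {
      readr::write_csv(feature_weights(m$model, 30), out(paste0("weights_", m$set, ".csv")))
      write_normative_model(m$model, out(paste0("model_", m$set, ".json")))
    }
  }
  report <- list(
    meta = bundle$meta,
    accuracy = accuracy,
    severity_models = bundle$severity_models,
    subgroups = list(summary = bundle$subgroups$summary,
                     kruskal = bundle$subgroups$kruskal,
                     delayed_vs_advanced = bundle$subgroups$delayed_vs_advanced),
    sweep = tibble::as_tibble(bundle$sweep),
    sex = list(ratio = bundle$sex$ratio, ddi_by_sex = bundle$sex$ddi_by_sex,
               male_only = bundle$sex$male_only),
    ordinal = tidy(bundle$ordinal)
  )
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  writeLines(render_report_md(bundle), out("report.md"))
  yaml::write_yaml(serializable_config(config), out("config.yaml"))
  invisible(config$output_dir)
}

serializable_config <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$simulation)) {
    cfg$simulation <- unclass(cfg$simulation)
    cfg$simulation$residual_sd <- as.list(cfg$simulation$residual_sd)
  }
  cfg
}

render_report_md <- function(bundle) {
  sm <- bundle$severity_models
  sg <- bundle$subgroups
  c(
    "# Normative-deviation analysis report",
    "",
    sprintf("seed: %d | backend: %s | config hash: %s | version: %s",
            bundle$meta$seed, bundle$meta$backend, bundle$meta$config_hash,
            bundle$meta$version),
    "",
    "## Model accuracy (cross-validated, TDC)",
    purrr::map_chr(bundle$models, function(m) {
      sprintf("- %s: CV mean r = %.3f [%.3f, %.3f]; ASD test r = %.3f [%.3f, %.3f]",
              m$set, m$cv$mean_r, m$cv$ci_low, m$cv$ci_high,
              m$test$r, m$test$ci_low, m$test$ci_high)
    }),
    "",
    "## DDI vs severity (Spearman, BH-corrected across metric sets)",
    purrr::map_chr(seq_len(nrow(sm)), function(i) {
      sprintf("- %s: rho = %.3f [%.3f, %.3f], p = %.4f, q = %.4f",
              sm$set[i], sm$r[i], sm$ci_low[i], sm$ci_high[i], sm$p[i], sm$q[i])
    }),
    "",
    "## Developmental subgroups",
    purrr::map_chr(seq_len(nrow(sg$summary)), function(i) {
      sprintf("- %s: n = %d, severity %.2f (%.2f)", sg$summary$subgroup[i],
              sg$summary$n[i], sg$summary$mean_severity[i], sg$summary$sd_severity[i])
    }),
    sprintf("- Kruskal-Wallis H = %.2f, p = %.4f", sg$kruskal$h, sg$kruskal$p),
    sprintf("- Delayed vs Advanced: d = %.2f, CLES = %.2f, U = %.1f, p = %.4f",
            sg$delayed_vs_advanced$d, sg$delayed_vs_advanced$cles,
            sg$delayed_vs_advanced$u, sg$delayed_vs_advanced$p_u)
  )
}
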