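#' Assemble a multimodal feature matrix from a cohort
#'
#' Concatenates the requested metric tables column-wise in the fixed order
#' volume, area, thickness, FA, ADC, naming features `"<metric>:<region>"`.
#' With the default atlas sizes this yields 68 features per anatomical
#' metric, 176 per diffusion metric and 556 for all five combined. The
#' cohort must already be aligned on the requested metrics, so the matrix
#' has no missing cells.
#'
#' @param cohort An aligned `ddi_cohort`.
#' @param metrics Subset of `c("volume","area","thickness","fa","adc")`.
#' @param group Optional diagnostic group to restrict to (`"TDC"` for
#'   normative training, `"ASD"` for scoring).
#' @return A `feature_matrix`: list with `ids`, `feature_names`, `x`
#'   (participants x features), `ages` and `metrics`.
#' @export
assemble_features <- function(cohort, metrics = names(cohort$tables), group = NULL) {
  stopifnot(inherits(cohort, "ddi_cohort"))
  metrics <- METRICS[METRICS %in% metrics]
  if (length(metrics) == 0) abort("no known metric requested")
  missing_tab <- setdiff(metrics, names(cohort$tables))
  if (length(missing_tab)) {
    abort(paste0("cohort lacks metric table(s): ", paste(missing_tab, collapse = ", "),
                 "; align the cohort on the requested metrics first"))
  }
  if (!is.null(group)) cohort <- cohort_subset(cohort, group)
  ids <- cohort$phenotypes$id
  blocks <- purrr::map(metrics, function(m) {
    tab <- cohort$tables[[m]]
    if (!all(ids %in% tab$id)) {
      abort(sprintf("participants missing from the '%s' table; align the cohort first", m))
    }
    v <- table_values(tab)[ids, , drop = FALSE]
    colnames(v) <- paste0(m, ":", colnames(v))
    v
  })
  x <- do.call(cbind, blocks)
  if (anyNA(x)) abort("feature matrix contains missing cells")
  structure(list(ids = ids, feature_names = colnames(x), x = x,
                 ages = cohort$phenotypes$age, metrics = metrics),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d participants x %d features (%s)\n",
              nrow(x$x), ncol(x$x), paste(x$metrics, collapse = ", ")))
  invisible(x)
}

standardize_fit <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, sd)
  constant <- scale == 0
  if (any(constant)) {
    warn(sprintf("%d constant feature(s) standardized to zero", sum(constant)))
    scale[constant] <- 1
  }
  list(center = center, scale = scale)
}

standardize_apply <- function(x, std) {
  sweep(sweep(x, 2, std$center, "-"), 2, std$scale, "/")
}

# core linear fits on an already-standardized design; all backends return
# weights in standardized-feature units plus an intercept
fit_core <- function(xs, y, backend) {
  switch(backend,
    linear_svr = {
      m <- e1071::svm(x = xs, y = y, type = "eps-regression",
                      kernel = "linear", cost = 1, epsilon = 0.1,
                      scale = FALSE)
      list(weights = drop(crossprod(m$coefs, m$SV)), intercept = -m$rho)
    },
    l1_linear = {
      foldid <- rep_len(seq_len(10), length(y))  # deterministic folds
      cvm <- glmnet::cv.glmnet(xs, y, alpha = 1, foldid = foldid,
                               standardize = FALSE)
      cf <- as.numeric(coef(cvm, s = "lambda.min"))
      list(weights = cf[-1], intercept = cf[1])
    },
    bayesian_linear = fit_bayesian_ridge(xs, y)
  )
}

# Conjugate Gaussian linear regression with evidence-maximised prior and
# noise precisions (MacKay fixed-point updates), computed through the SVD
# of the design for stability at p >> n.
fit_bayesian_ridge <- function(x, y, max_iter = 300, tol = 1e-9) {
  n <- nrow(x)
  ybar <- mean(y)
  yc <- y - ybar
  sv <- svd(x)
  d2 <- sv$d^2
  uty <- drop(crossprod(sv$u, yc))
  alpha <- 1
  beta <- 1 / max(stats::var(yc), 1e-12)
  w <- rep(0, ncol(x))
  for (i in seq_len(max_iter)) {
    m_rot <- beta * sv$d * uty / (alpha + beta * d2)
    w_new <- drop(sv$v %*% m_rot)
    gam <- sum(beta * d2 / (alpha + beta * d2))
    rss <- sum((yc - x %*% w_new)^2)
    alpha_new <- gam / max(sum(w_new^2), 1e-12)
    beta_new <- max(n - gam, 1e-9) / max(rss, 1e-12)
    done <- abs(log(alpha_new / alpha)) < tol && abs(log(beta_new / beta)) < tol
    alpha <- alpha_new; beta <- beta_new; w <- w_new
    if (done) break
  }
  list(weights = w, intercept = ybar,
       hyper = c(alpha = alpha, beta = beta))
}

#' Fit a normative age-prediction model
#'
#' Standardizes each feature by its training mean and SD (frozen into the
#' model), then fits a linear predictor of chronological age. The model
#' must be trained on the normative (typically developing) sample only:
#' deviations of a clinical cohort are later scored against it. Weights
#' are reported in standardized-feature units (years per SD), making them
#' comparable across metrics with different physical units.
#'
#' Backends: `"linear_svr"` (default; epsilon-insensitive support vector
#' regression with a linear kernel, `C = 1`, `epsilon = 0.1` — the
#' reference implementation's defaults), `"l1_linear"` (lasso with the
#' penalty chosen by internal 10-fold cross-validation on deterministic
#' folds) and `"bayesian_linear"` (conjugate Gaussian regression with
#' evidence-maximised hyperparameters).
#'
#' @param features A `feature_matrix` of the training sample (n >= 10).
#' @param backend Model family, see above.
#' @return A `normative_model` with frozen standardization parameters,
#'   weights, intercept and training metadata.
#' @export
fit_normative <- function(features, backend = c("linear_svr", "l1_linear",
                                                "bayesian_linear")) {
  stopifnot(inherits(features, "feature_matrix"))
  backend <- match.arg(backend)
  if (nrow(features$x) < 10) abort("need at least 10 training participants")
  std <- standardize_fit(features$x)
  xs <- standardize_apply(features$x, std)
  core <- fit_core(xs, features$ages, backend)
  pred <- drop(xs %*% core$weights) + core$intercept
  structure(list(
    backend = backend,
    feature_names = features$feature_names,
    center = std$center, scale = std$scale,
    weights = unname(core$weights), intercept = unname(core$intercept),
    train_ids = features$ids, n_train = length(features$ids),
    training_r = if (sd(pred) > 0) cor(pred, features$ages) else NA_real_
  ), class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf("<normative_model> backend = %s, %d features, n_train = %d, training r = %.3f\n",
              x$backend, length(x$weights), x$n_train, x$training_r))
  invisible(x)
}

#' Predict brain age for a feature matrix
#'
#' Applies the model's frozen standardization and linear weights. Feature
#' names must match the model's exactly and in order; no silent positional
#' or reordered matching is performed.
#'
#' @param model A `normative_model`.
#' @param features A `feature_matrix`.
#' @return Tibble `id`, `age`, `brain_age`.
#' @export
predict_brain_age <- function(model, features) {
  stopifnot(inherits(model, "normative_model"), inherits(features, "feature_matrix"))
  if (!identical(features$feature_names, model$feature_names)) {
    abort("feature names do not match the model (same names, same order, required)")
  }
  xs <- standardize_apply(features$x, list(center = model$center, scale = model$scale))
  tibble::tibble(id = features$ids, age = features$ages,
                 brain_age = drop(xs %*% model$weights) + model$intercept)
}

#' Repeated k-fold cross-validated age-prediction accuracy
#'
#' One repeat shuffles the participants (seeded), splits them into `k`
#' folds, refits the model on each training split (standardization
#' recomputed from the training fold only, so no information leaks into
#' the held-out fold), predicts the held-out fold, pools all out-of-fold
#' predictions and records a single Pearson r against chronological age.
#' The summary is the mean of the per-repeat r values with a 95% CI from
#' their 2.5th and 97.5th percentiles.
#'
#' @param features A `feature_matrix` (training sample).
#' @param backend Model family, see [fit_normative()].
#' @param k Number of folds (default 10).
#' @param repeats Number of repeats (>= 2; 1000 reproduces the full
#'   protocol, a few dozen give a stable mean).
#' @param seed Integer seed for the fold shuffles.
#' @return A `cv_accuracy` object.
#' @export
repeated_cv <- function(features, backend = "linear_svr", k = 10, repeats = 100,
                        seed = 1) {
  stopifnot(inherits(features, "feature_matrix"))
  n <- nrow(features$x)
  if (n < k) abort("need at least k participants")
  if (repeats < 2) abort("repeats must be >= 2 for a CI over repeats")
  set.seed(seed)
  r_values <- vapply(seq_len(repeats), function(rep_i) {
    idx <- sample.int(n)
    fold <- rep_len(seq_len(k), n)
    pred <- numeric(n)
    for (f in seq_len(k)) {
      test <- idx[fold == f]
      train <- idx[fold != f]
      std <- suppressWarnings(standardize_fit(features$x[train, , drop = FALSE]))
      xs_tr <- standardize_apply(features$x[train, , drop = FALSE], std)
      xs_te <- standardize_apply(features$x[test, , drop = FALSE], std)
      core <- fit_core(xs_tr, features$ages[train], backend)
      pred[test] <- drop(xs_te %*% core$weights) + core$intercept
    }
    cor(pred, features$ages)
  }, numeric(1))
  ci <- unname(quantile(r_values, c(0.025, 0.975)))
  structure(list(r_values = r_values, mean_r = mean(r_values),
                 ci_low = ci[1], ci_high = ci[2],
                 k = k, repeats = repeats, backend = backend, n = n),
            class = "cv_accuracy")
}

#' @export
print.cv_accuracy <- function(x, ...) {
  cat(sprintf("<cv_accuracy> %d-fold x %d repeats (%s, n = %d): mean r = %.3f, 95%% CI [%.3f, %.3f]\n",
              x$k, x$repeats, x$backend, x$n, x$mean_r, x$ci_low, x$ci_high))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cv_accuracy <- function(x, ...) {
  tibble::tibble(repeat_id = seq_along(x$r_values), r = x$r_values)
}

#' @exportS3Method generics::glance
glance.cv_accuracy <- function(x, ...) {
  tibble::tibble(mean_r = x$mean_r, ci_low = x$ci_low, ci_high = x$ci_high,
                 k = x$k, repeats = x$repeats, backend = x$backend, n = x$n)
}

#' Test accuracy of a normative model on an external sample
#'
#' Pearson correlation between predicted and chronological age in a group
#' disjoint from the training sample, with a 95% CI via the Fisher
#' transform and `SE = 1 / sqrt(n - 3)`.
#'
#' @param model A `normative_model`.
#' @param features A `feature_matrix` disjoint from the training ids.
#' @return One-row tibble `r`, `n`, `ci_low`, `ci_high`.
#' @export
external_test_accuracy <- function(model, features) {
  stopifnot(inherits(model, "normative_model"), inherits(features, "feature_matrix"))
  if (length(intersect(features$ids, model$train_ids)) > 0) {
    abort("test sample overlaps the training sample")
  }
  n <- length(features$ids)
  if (n <= 3) abort("need more than 3 test participants")
  pred <- predict_brain_age(model, features)
  r <- cor(pred$brain_age, pred$age)
  ci <- if (abs(r) < 1) fisher_ci(r, n) else tibble::tibble(ci_low = r, ci_high = r)
  tibble::tibble(r = r, n = n, ci_low = ci$ci_low, ci_high = ci$ci_high)
}

#' Ranked feature weights of a normative model
#'
#' @param model A `normative_model`.
#' @param top_n How many features to keep (by |weight|, descending; ties
#'   broken by feature name). Larger than the feature count gives all.
#' @return Tibble `rank`, `feature`, `metric`, `region`, `weight`.
#' @export
feature_weights <- function(model, top_n = 30) {
  stopifnot(inherits(model, "normative_model"))
  w <- model$weights
  if (all(w == 0)) {
    warn("all feature weights are zero")
    return(tibble::tibble(rank = integer(), feature = character(),
                          metric = character(), region = character(),
                          weight = double()))
  }
  ord <- order(-abs(w), model$feature_names)
  keep <- head(ord, top_n)
  parts <- strsplit(model$feature_names[keep], ":", fixed = TRUE)
  tibble::tibble(
    rank = seq_along(keep),
    feature = model$feature_names[keep],
    metric = vapply(parts, `[`, character(1), 1),
    region = vapply(parts, `[`, character(1), 2),
    weight = w[keep]
  )
}

#' @exportS3Method generics::tidy
tidy.normative_model <- function(x, ...) {
  feature_weights(x, top_n = length(x$weights))
}

#' @exportS3Method generics::glance
glance.normative_model <- function(x, ...) {
  tibble::tibble(backend = x$backend, n_features = length(x$weights),
                 n_train = x$n_train, training_r = x$training_r)
}
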