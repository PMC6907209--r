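test_that("feature assembly yields the canonical counts and ordering", {
  g <- generate_cohort(sim_config(n_tdc = 20, n_asd = 10, seed = 1))
  co <- g$cohort
  expect_equal(length(assemble_features(co, "fa")$feature_names), 176)
  expect_equal(length(assemble_features(co, "adc")$feature_names), 176)
  expect_equal(length(assemble_features(co, "thickness")$feature_names), 68)
  all5 <- assemble_features(co, c("fa", "adc", "volume", "area", "thickness"))
  expect_equal(length(all5$feature_names), 556)
  # fixed block order regardless of request order
  expect_equal(unique(sub(":.*", "", all5$feature_names)),
               c("volume", "area", "thickness", "fa", "adc"))
  expect_true(all(grepl("^[a-z]+:", all5$feature_names)))
})

test_that("assembly demands an aligned cohort", {
  ph <- tiny_phenotypes(4)
  fa <- metric_table(tibble::tibble(id = sprintf("s%d", 1:4), r1 = 0.4), "fa")
  thick <- metric_table(tibble::tibble(id = sprintf("s%d", 1:2), r1 = 2.4), "thickness")
  co <- align_cohort(ph, list(fa = fa, thickness = thick), required_metrics = "fa")
  expect_error(assemble_features(co, c("fa", "thickness")), "align")
})

test_that("noiseless training data is fit essentially perfectly by every backend", {
  g <- generate_cohort(noiseless_config(n_tdc = 60, n_asd = 10, seed = 2))
  f <- assemble_features(g$cohort, "fa", group = "TDC")
  for (backend in c("linear_svr", "l1_linear", "bayesian_linear")) {
    m <- fit_normative(f, backend = backend)
    expect_gte(m$training_r, 0.999)
    pred <- predict_brain_age(m, f)
    expect_equal(cor(pred$brain_age, pred$age), m$training_r)
  }
})

test_that("degenerate designs are handled: duplicate and constant columns", {
  set.seed(3)
  x <- matrix(rnorm(50 * 4), 50, 4)
  ages <- 6 + 0.5 * x[, 1] + 10
  x <- cbind(x, x[, 1], 1)  # duplicated informative column plus a constant
  colnames(x) <- paste0("fa:r", 1:6)
  f <- raw_features(x, ages)
  expect_warning(m <- fit_normative(f, backend = "bayesian_linear"), "constant")
  expect_gt(m$training_r, 0.99)
  # duplicated columns split the weight mass without breaking the fit
  expect_equal(m$weights[1], m$weights[5], tolerance = 1e-6)
})

test_that("l1 backend concentrates weight mass on the informative features", {
  set.seed(4)
  n <- 120; p <- 40
  x <- matrix(rnorm(n * p), n, p)
  ages <- runif(n, 6, 25)
  x[, 1:5] <- 0.3 * x[, 1:5] + 0.2 * ages
  f <- raw_features(x, ages)
  m <- fit_normative(f, backend = "l1_linear")
  w <- abs(m$weights)
  expect_gte(sum(w[1:5]) / sum(w), 0.9)
})

test_that("prediction refuses mismatched or reordered features", {
  g <- generate_cohort(sim_config(n_tdc = 20, n_asd = 10, seed = 5))
  f <- assemble_features(g$cohort, "fa", group = "TDC")
  m <- fit_normative(f, backend = "bayesian_linear")
  perm <- f
  shuffle <- c(2:ncol(perm$x), 1)
  perm$x <- perm$x[, shuffle]
  perm$feature_names <- perm$feature_names[shuffle]
  expect_error(predict_brain_age(m, perm), "match the model")
})

test_that("an induced effective-age shift is recovered in the predicted gap", {
  g <- generate_cohort(sim_config(n_tdc = 150, n_asd = 60, deviation_sd = 2,
                                  noise_scale = 0.1, seed = 6))
  f <- assemble_features(g$cohort, c("fa", "adc"), group = "TDC")
  m <- fit_normative(f)
  pred <- predict_brain_age(m, assemble_features(g$cohort, c("fa", "adc"), group = "ASD"))
  delta <- g$truth$delta$delta[match(pred$id, g$truth$delta$id)]
  expect_lt(max(abs((pred$brain_age - pred$age) - delta)), 0.5)
})

test_that("repeated CV is seeded, leak-free and honest under the null", {
  g <- generate_cohort(sim_config(n_tdc = 200, n_asd = 10, seed = 7))
  f <- assemble_features(g$cohort, "fa", group = "TDC")

  cv1 <- repeated_cv(f, backend = "bayesian_linear", repeats = 5, seed = 3)
  cv2 <- repeated_cv(f, backend = "bayesian_linear", repeats = 5, seed = 3)
  expect_identical(cv1$r_values, cv2$r_values)
  expect_true(all(cv1$r_values >= -1 & cv1$r_values <= 1))
  expect_lte(cv1$ci_low, cv1$mean_r)
  expect_gte(cv1$ci_high, cv1$mean_r)

  # ages independent of the brain: accuracy must not inflate; averaged over
  # data draws because a single spurious feature-age alignment can push one
  # dataset's CV correlation either way
  set.seed(8)
  null_means <- vapply(1:4, function(i) {
    null_f <- f
    null_f$ages <- runif(200, 6, 25)
    repeated_cv(null_f, backend = "linear_svr", repeats = 10, seed = i)$mean_r
  }, numeric(1))
  expect_lt(abs(mean(null_means)), 0.1)

  expect_error(repeated_cv(f, repeats = 1), "repeats")
})

test_that("mean CV accuracy is stable in the number of repeats", {
  g <- generate_cohort(sim_config(n_tdc = 120, n_asd = 10, seed = 9))
  f <- assemble_features(g$cohort, "fa", group = "TDC")
  cv_a <- repeated_cv(f, backend = "bayesian_linear", repeats = 50, seed = 1)
  cv_b <- repeated_cv(f, backend = "bayesian_linear", repeats = 100, seed = 2)
  expect_lt(abs(cv_a$mean_r - cv_b$mean_r), 0.01)
})

test_that("external test accuracy uses the Fisher CI and demands disjoint samples", {
  g <- generate_cohort(sim_config(n_tdc = 80, n_asd = 60, seed = 10))
  f_tdc <- assemble_features(g$cohort, "fa", group = "TDC")
  f_asd <- assemble_features(g$cohort, "fa", group = "ASD")
  m <- fit_normative(f_tdc, backend = "bayesian_linear")
  acc <- external_test_accuracy(m, f_asd)
  ci <- fisher_ci(acc$r, acc$n)
  expect_equal(c(acc$ci_low, acc$ci_high), c(ci$ci_low, ci$ci_high), tolerance = 1e-10)
  expect_error(external_test_accuracy(m, f_tdc), "overlaps")

  # n = 4 still runs, and the Fisher CI explodes at such n for any
  # non-extreme correlation
  tiny <- ddikit:::subset_features(f_asd, f_asd$ids[1:4])
  wide <- external_test_accuracy(m, tiny)
  expect_true(wide$ci_low >= -1 && wide$ci_high <= 1)
  for (r in seq(-0.95, 0.95, by = 0.19)) {
    ci <- fisher_ci(r, 4)
    expect_gt(ci$ci_high - ci$ci_low, 1)
  }
  tiny3 <- ddikit:::subset_features(f_asd, f_asd$ids[1:3])
  expect_error(external_test_accuracy(m, tiny3), "more than 3")
})

test_that("feature weights rank by magnitude with stable ties", {
  set.seed(11)
  x <- matrix(rnorm(60 * 6), 60, 6)
  ages <- 10 + 3 * x[, 4] + rnorm(60, 0, 0.2)
  f <- raw_features(x, ages)
  m <- fit_normative(f, backend = "bayesian_linear")
  fw <- feature_weights(m, top_n = 3)
  expect_equal(fw$feature[1], "fa:r4")
  full <- feature_weights(m, top_n = 100)
  expect_equal(nrow(full), 6)
  expect_true(all(diff(abs(full$weight)) <= 1e-12))

  zero <- m
  zero$weights <- rep(0, 6)
  expect_warning(fw0 <- feature_weights(zero), "zero")
  expect_equal(nrow(fw0), 0)
})

test_that("diffusion features dominate the combined model's top weights", {
  g <- generate_cohort(sim_config(n_tdc = 150, n_asd = 10, seed = 12))
  f <- assemble_features(g$cohort, c("volume", "area", "thickness", "fa", "adc"),
                         group = "TDC")
  m <- fit_normative(f)
  top <- feature_weights(m, top_n = 30)
  expect_gt(mean(top$metric %in% c("fa", "adc")), 0.5)
})

test_that("normative models survive a JSON round trip", {
  g <- generate_cohort(sim_config(n_tdc = 30, n_asd = 10, seed = 13))
  f <- assemble_features(g$cohort, "thickness", group = "TDC")
  m <- fit_normative(f, backend = "bayesian_linear")
  path <- withr::local_tempfile(fileext = ".json")
  write_normative_model(m, path)
  m2 <- read_normative_model(path)
  f_asd <- assemble_features(g$cohort, "thickness", group = "ASD")
  expect_equal(predict_brain_age(m2, f_asd)$brain_age,
               predict_brain_age(m, f_asd)$brain_age, tolerance = 1e-12)
})
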