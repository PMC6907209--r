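test_that("regional age correlation is exact on linear data and honest on noise", {
  ages <- seq(6, 25, length.out = 30)
  tab <- metric_table(
    tibble::tibble(id = sprintf("s%02d", 1:30),
                   up = 0.3 + 0.01 * ages,
                   down = 0.9 - 0.005 * ages,
                   flat = rep(0.5, 30)),
    metric = "fa",
    regions = region_info(c("up", "down", "flat"), tissue = "wm")
  )
  res <- regional_age_correlation(tab, ages)
  expect_equal(res$r[res$region == "up"], 1, tolerance = 1e-12)
  expect_equal(res$r[res$region == "down"], -1, tolerance = 1e-12)
  expect_true(is.na(res$r[res$region == "flat"]))   # flagged, excluded from FDR
  expect_true(is.na(res$q[res$region == "flat"]))
  expect_true(all(res$q >= res$p, na.rm = TRUE))
})

test_that("synthetic white-matter FA regions all correlate positively with age", {
  g <- generate_cohort(sim_config(n_tdc = 150, n_asd = 10, noise_scale = 0.5, seed = 9))
  tdc <- cohort_subset(g$cohort, "TDC")
  res <- regional_age_correlation(tdc$tables$fa, tdc$phenotypes$age)
  wm <- res[res$tissue == "wm", ]
  expect_true(all(wm$r > 0))
})

test_that("the flat-by-design area metric gives a near-empty joint set", {
  g <- generate_cohort(sim_config(n_tdc = 150, n_asd = 150, seed = 14))
  tdc <- cohort_subset(g$cohort, "TDC")
  asd <- cohort_subset(g$cohort, "ASD")
  ct <- regional_age_correlation(tdc$tables$area, tdc$phenotypes$age)
  ca <- regional_age_correlation(asd$tables$area, asd$phenotypes$age)
  joint <- joint_significant_regions(ct, ca)
  expect_lt(nrow(joint), 68 * 0.1)
})

test_that("permuted ages yield a near-nominal false-positive rate", {
  g <- generate_cohort(sim_config(n_tdc = 100, n_asd = 10, seed = 10))
  tdc <- cohort_subset(g$cohort, "TDC")
  set.seed(1)
  res <- regional_age_correlation(tdc$tables$adc, sample(tdc$phenotypes$age))
  expect_lt(mean(abs(res$r)), 0.12)
  expect_lt(mean(res$p < 0.05), 0.15)
})

test_that("joint significance screening keeps only regions significant in both groups", {
  base <- tibble::tibble(metric = "fa", region = c("a", "b", "c"),
                         hemisphere = "left", tissue = "wm", n = 50)
  tdc <- dplyr::mutate(base, r = c(0.5, 0.5, 0.1), p = c(0.001, 0.001, 0.5), q = p)
  asd <- dplyr::mutate(base, r = c(0.4, 0.1, 0.4), p = c(0.01, 0.6, 0.01), q = p)
  joint <- joint_significant_regions(tdc, asd)
  expect_equal(joint$region, "a")
  all_sig <- joint_significant_regions(tdc, dplyr::mutate(tdc, r = r * 0.9))
  expect_equal(nrow(all_sig), 2)  # "c" is non-significant in both
  expect_error(joint_significant_regions(tdc, asd[1:2, ]), "universe")
})

test_that("compare_correlations matches the closed form to 1e-10", {
  cmp <- compare_correlations(0.5, 103, 0.3, 103)
  z_oracle <- (atanh(0.5) - atanh(0.3)) / sqrt(1 / 100 + 1 / 100)
  expect_equal(cmp$z, z_oracle, tolerance = 1e-10)
  expect_equal(round(cmp$z, 3), 1.696)
  expect_equal(compare_correlations(0.4, 60, 0.4, 80)$z, 0)
  expect_equal(compare_correlations(0.4, 60, 0.4, 80)$p, 1)
  swap <- compare_correlations(0.3, 103, 0.5, 103)
  expect_equal(swap$z, -cmp$z)
  expect_equal(swap$p, cmp$p)
  expect_error(compare_correlations(1, 10, 0.5, 10), "magnitude 1")
})

test_that("fdr_bh implements the step-up rule and dominates Bonferroni", {
  res <- fdr_bh(c(0.01, 0.02, 0.03, 0.04))
  expect_true(all(res$reject))
  expect_equal(fdr_bh(0.04)$q, 0.04)
  expect_true(fdr_bh(0.04)$reject)
  expect_false(any(fdr_bh(rep(1, 5))$reject))
  expect_equal(nrow(fdr_bh(double())), 0)

  set.seed(11)
  for (i in 1:20) {
    p <- runif(50)^2
    bh <- fdr_bh(p)
    bonf <- p <= 0.05 / length(p)
    expect_true(all(bh$reject[bonf]))            # BH rejects whatever Bonferroni does
    expect_true(all(diff(bh$q[order(bh$p)]) >= -1e-15))
  }
})

test_that("flattened ASD maturation is recovered as reduced |r| in ASD", {
  g <- generate_cohort(sim_config(n_tdc = 160, n_asd = 160, deviation_sd = 0, seed = 12))
  co <- g$cohort
  # flatten the ASD age effect: shrink the age-predicted part of each
  # region while keeping the residual noise at its original scale
  ph <- co$phenotypes
  fa <- co$tables$fa
  asd_rows <- which(fa$id %in% ph$id[ph$group == "ASD"])
  asd_age <- ph$age[match(fa$id[asd_rows], ph$id)]
  flat <- tibble::as_tibble(fa)
  for (j in 2:ncol(flat)) {
    v <- flat[[j]][asd_rows]
    fit <- lm(v ~ asd_age)
    flat[[j]][asd_rows] <- mean(fitted(fit)) + 0.4 * (fitted(fit) - mean(fitted(fit))) +
      resid(fit)
  }
  co$tables$fa <- metric_table(flat, "fa", regions = attr(fa, "regions"))
  cmp <- compare_maturation(co, metrics = "fa")
  expect_gt(nrow(cmp), 10)
  expect_gte(mean(abs(cmp$r_tdc) > abs(cmp$r_asd)), 0.95)
})

test_that("regional effect sizes are antisymmetric and directionally correct", {
  g <- generate_cohort(sim_config(n_tdc = 120, n_asd = 120, deviation_sd = 1.5, seed = 13))
  co <- g$cohort
  truth <- g$truth$delta
  tdc_fa <- cohort_subset(co, "TDC")$tables$fa
  asd_fa <- cohort_subset(co, "ASD")$tables$fa
  # synthetic Advanced subgroup: delta >= 1 SD
  adv_ids <- truth$id[truth$delta >= 1.5]
  adv_rows <- tibble::as_tibble(asd_fa)[asd_fa$id %in% adv_ids, ]
  adv_tab <- metric_table(adv_rows, "fa", regions = attr(asd_fa, "regions"))

  es <- regional_group_effectsize(adv_tab, tdc_fa)
  wm <- es[es$tissue == "wm", ]
  # advanced maturation reads as predominantly higher wm FA
  expect_gt(mean(wm$d > 0), 0.6)
  expect_gt(mean(wm$d), 0)

  sw <- regional_group_effectsize(tdc_fa, adv_tab)
  expect_equal(sw$d, -es$d, tolerance = 1e-12)

  same <- regional_group_effectsize(tdc_fa, tdc_fa)
  expect_true(all(same$d == 0))
})
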