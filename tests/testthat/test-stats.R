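test_that("fisher_ci matches the closed form and its published worked example", {
  # r = -0.20, n = 176: the CI bounds round to [-0.34, -0.05]
  ci <- fisher_ci(-0.20, 176)
  expect_equal(round(ci$ci_low, 2), -0.34)
  expect_equal(round(ci$ci_high, 2), -0.05)

  # independent evaluation of the atanh/tanh formula
  oracle <- function(r, n, conf = 0.95) {
    z <- 0.5 * log((1 + r) / (1 - r))
    h <- qnorm(1 - (1 - conf) / 2) / sqrt(n - 3)
    c(tanh(z - h), tanh(z + h))
  }
  ci2 <- fisher_ci(0.5, 28)
  expect_equal(c(ci2$ci_low, ci2$ci_high), oracle(0.5, 28), tolerance = 1e-10)
  expect_equal(round(c(ci2$ci_low, ci2$ci_high), 3), c(0.156, 0.736))

  ci0 <- fisher_ci(0, 50)
  expect_equal(ci0$ci_low, -ci0$ci_high, tolerance = 1e-12)
})

test_that("fisher_ci width shrinks with n and always contains r", {
  rs <- c(-0.8, -0.2, 0, 0.3, 0.9)
  for (r in rs) {
    widths <- vapply(c(10, 30, 100, 1000), function(n) {
      ci <- fisher_ci(r, n)
      expect_lte(ci$ci_low, r)
      expect_gte(ci$ci_high, r)
      ci$ci_high - ci$ci_low
    }, numeric(1))
    expect_true(all(diff(widths) < 0))
  }
  expect_error(fisher_ci(0.5, 3), "n > 3")
  expect_error(fisher_ci(1, 10), "\\|r\\| < 1")
})

test_that("spearman_with_ci matches rank-based brute force", {
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  rep1 <- spearman_with_ci(x, y)
  expect_equal(rep1$r, cor(rank(x), rank(y)))  # brute force over rank pairs
  expect_equal(rep1$r, 0.8)
  rep2 <- spearman_with_ci(x, rev(y))
  expect_equal(rep2$r, -rep1$r)
  # strictly monotone transform gives rho = 1
  z <- rnorm(20)
  expect_equal(spearman_with_ci(z, exp(z))$r, 1)
  expect_error(spearman_with_ci(rep(1, 10), rnorm(10)), "constant")
})

test_that("cohens_d agrees between raw and summary forms", {
  expect_equal(cohens_d(c(2, 4), c(1, 3)), 1 / sqrt(2), tolerance = 1e-12)
  # Delayed vs Advanced severity from subgroup summary statistics
  d <- cohens_d_from_summary(8.00, 1.19, 27, 6.47, 1.87, 19)
  expect_equal(round(d, 2), 1.02)
  set.seed(1)
  g1 <- rnorm(23, 1, 2); g2 <- rnorm(31, 0, 1.5)
  expect_equal(cohens_d(g1, g2),
               cohens_d_from_summary(mean(g1), sd(g1), 23, mean(g2), sd(g2), 31),
               tolerance = 1e-12)
  expect_equal(cohens_d(g1, g2), -cohens_d(g2, g1), tolerance = 1e-12)
  expect_equal(cohens_d(g1, g1), 0)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled")
})

test_that("cles counts wins plus half-ties over all cross pairs", {
  # brute-force pair enumeration oracle
  brute <- function(a, b) {
    wins <- sum(outer(a, b, ">")); ties <- sum(outer(a, b, "=="))
    (wins + 0.5 * ties) / (length(a) * length(b))
  }
  expect_equal(cles(c(3, 4, 5), c(1, 2, 3)), (8 + 0.5) / 9)
  expect_equal(cles(1, 1), 0.5)
  expect_equal(cles(c(3, 4, 5), c(1, 2, 3)), brute(c(3, 4, 5), c(1, 2, 3)))
  # summary form: printed U over n1*n2
  expect_equal(round(380.5 / (27 * 19), 2), 0.74)
  set.seed(2)
  for (i in 1:10) {
    a <- sample(1:10, 17, replace = TRUE); b <- sample(1:10, 13, replace = TRUE)
    expect_equal(cles(a, b), brute(a, b), tolerance = 1e-12)
    expect_equal(cles(a, b) + cles(b, a), 1, tolerance = 1e-12)
  }
})

test_that("mann_whitney U is consistent with cles and brute force", {
  mw <- mann_whitney(c(3, 4, 5), c(1, 2, 3))
  expect_equal(mw$u, 8.5)
  expect_equal(mw$u / (mw$n1 * mw$n2), cles(c(3, 4, 5), c(1, 2, 3)))
  all_above <- mann_whitney(c(10, 11), c(1, 2, 3))
  expect_equal(all_above$u, 2 * 3)
  set.seed(3)
  a <- sample(1:8, 20, replace = TRUE); b <- sample(1:8, 15, replace = TRUE)
  m1 <- mann_whitney(a, b); m2 <- mann_whitney(b, a)
  expect_equal(m1$u + m2$u, 20 * 15)
  expect_equal(m1$p, m2$p, tolerance = 1e-12)
})

test_that("kruskal_wallis matches the hand rank computation", {
  # groups {1,2},{3,4},{5,6}: ranks 1..6, no ties
  # H = 12/(N(N+1)) * sum(R_i^2/n_i) - 3(N+1) = 12/42 * 89.5 - 21
  kw <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(kw$h, 12 / 42 * (3^2 / 2 + 7^2 / 2 + 11^2 / 2) - 21, tolerance = 1e-12)
  expect_equal(kw$df, 2)
  expect_gt(kw$p, 0.05)  # 4.571 on 2 df does not reach 5.99
  same <- kruskal_wallis(list(c(1, 2, 3), c(2, 1, 3)))
  expect_equal(same$h, 0, tolerance = 1e-12)
  expect_equal(kruskal_wallis(list(rep(4, 3), rep(4, 5)))$h, 0)
})

test_that("label permutation keeps the Kruskal-Wallis size near nominal", {
  set.seed(4)
  vals <- rnorm(45)
  rejections <- replicate(200, {
    g <- split(sample(vals), rep(1:3, each = 15))
    kruskal_wallis(g)$p < 0.05
  })
  expect_gt(mean(rejections), 0.005)
  expect_lt(mean(rejections), 0.12)
})

test_that("chi2_2x2 reproduces the worked sex-ratio example without correction", {
  # TDC 161 M / 59 F vs ASD 203 M / 44 F
  res <- chi2_2x2(matrix(c(161, 203, 59, 44), 2))
  expect_equal(round(res$chi2, 2), 5.49)
  expect_equal(res$df, 1)
  expect_lt(res$p, 0.05)
  expect_equal(chi2_2x2(matrix(c(20, 10, 10, 20), 2))$chi2, 20 / 3, tolerance = 1e-12)
  expect_equal(chi2_2x2(matrix(c(10, 20, 20, 40), 2))$chi2, 0, tolerance = 1e-12)
  expect_error(chi2_2x2(matrix(c(0, 0, 5, 5), 2)), "margins")
})

test_that("ordinal_fit recovers proportional-odds coefficients", {
  zeta <- qlogis(seq(0.1, 0.9, 0.1))
  simulate_po <- function(n, beta, x) {
    # cumulative-logit draw: P(Y <= k | x) = plogis(zeta_k - beta * x)
    u <- runif(n)
    1L + rowSums(outer(u, seq_along(zeta), function(ui, k) ui > plogis(zeta[k] - beta * x)))
  }
  set.seed(5)
  est <- replicate(100, {
    x <- rnorm(176)
    y <- simulate_po(176, -0.32, x)
    tidy(ordinal_fit(y, tibble::tibble(x = x)))$estimate
  })
  expect_lt(abs(mean(est) + 0.32), 0.1)

  # null covariate: estimate near zero
  set.seed(6)
  x <- rnorm(300); y <- simulate_po(300, 0, x)
  nullfit <- tidy(ordinal_fit(y, tibble::tibble(x = x)))
  expect_lt(abs(nullfit$estimate), 0.25)

  # severity increasing in a covariate gives a positive coefficient
  set.seed(7)
  x <- rnorm(200)
  y <- pmin(pmax(round(5.5 + 1.5 * x + rnorm(200, 0, 0.8)), 1), 10)
  posfit <- ordinal_fit(y, tibble::tibble(x = x))
  expect_gt(tidy(posfit)$estimate, 0)
  expect_true(all(diff(posfit$thresholds) > 0))
  expect_error(ordinal_fit(rep(4, 20), tibble::tibble(x = rnorm(20))), "two levels")
})

test_that("effect_size_report bundles d, cles and the U test coherently", {
  set.seed(8)
  g1 <- sample(1:10, 27, replace = TRUE); g2 <- sample(1:10, 19, replace = TRUE)
  rep <- effect_size_report(g1, g2)
  expect_equal(rep$cles, cles(g1, g2))
  expect_equal(rep$u, cles(g1, g2) * 27 * 19)
  expect_equal(rep$d, cohens_d(g1, g2))
})
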