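test_that("recovery ratio follows its definition and sign convention", {
  expect_equal(rfma_ratio(30, 45), 0.5)
  expect_equal(rfma_ratio(40, 40), 0)
  expect_equal(rfma_ratio(40, 30), -0.25)
  expect_error(rfma_ratio(0, 10), "baseline")
})

test_that("Welch t from summaries matches t.test on matching samples", {
  same <- welch_t_from_summary(5, 2, 10, 5, 2, 10)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # construct samples with exactly the requested summaries and compare
  set.seed(1)
  mk <- function(n, m, s) { x <- rnorm(n); m + s * scale(x)[, 1] }
  x1 <- mk(14, 3.2, 1.1); x2 <- mk(19, 2.4, 2.3)
  ours <- welch_t_from_summary(3.2, 1.1, 14, 2.4, 2.3, 19)
  ref <- t.test(x1, x2)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-9)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
})

test_that("chi-squared without continuity correction matches chisq.test", {
  res <- chi_square_2x2(12, 17, 19, 9)
  ref <- chisq.test(matrix(c(12, 17, 19, 9), 2, byrow = TRUE),
                    correct = FALSE)
  expect_equal(res$chisq, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)
  # perfectly proportional table
  prop <- chi_square_2x2(10, 20, 20, 40)
  expect_equal(prop$chisq, 0)
  expect_equal(prop$p, 1)
  expect_error(chi_square_2x2(0, 0, 5, 5), "margin")
})

test_that("Bonferroni threshold is alpha over m", {
  expect_equal(bonferroni_threshold(0.05, 8), 0.00625)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 5), 0.01)
})

test_that("partial Spearman reduces to plain Spearman and removes confounds", {
  # hand check with averaged tie ranks: ranks(y) = (1, 2, 3.5, 5, 3.5),
  # rho = 8 / sqrt(10 * 9.5)
  x <- 1:5; y <- c(5, 6, 7, 8, 7)
  expect_equal(partial_spearman(x, y)$rho, 8 / sqrt(95), tolerance = 1e-12)
  expect_equal(partial_spearman(x, y)$rho,
               cor(x, y, method = "spearman"), tolerance = 1e-12)
  # monotone invariance
  set.seed(2)
  xx <- rnorm(30)
  expect_equal(partial_spearman(xx, xx^3)$rho, 1)
  # shared confound is removed
  rhos <- vapply(1:200, function(r) {
    set.seed(400 + r)
    z <- rnorm(100)
    a <- z + rnorm(100)
    b <- z + rnorm(100)
    partial_spearman(a, b, covariates = z)$rho
  }, 0)
  expect_lt(abs(mean(rhos)), 0.05)
  raw <- vapply(1:50, function(r) {
    set.seed(400 + r)
    z <- rnorm(100)
    a <- z + rnorm(100)
    b <- z + rnorm(100)
    partial_spearman(a, b)$rho
  }, 0)
  expect_gt(mean(raw), 0.3) # confounded without adjustment
  expect_error(partial_spearman(rep(1, 10), rnorm(10)), "constant")
})

test_that("plain-Spearman p approximation matches cor.test's t form", {
  set.seed(3)
  x <- rnorm(20); y <- rnorm(20)
  ours <- partial_spearman(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)
})

test_that("RM-ANCOVA group effect has correct size and power", {
  simulate_kd <- function(delta, n = 20, seed) {
    set.seed(seed)
    subj_mean <- c(rnorm(n, 0, 1), rnorm(n, delta, 1))
    kd <- outer(subj_mean, rep(1, 10)) + matrix(rnorm(2 * n * 10, 0, 0.3),
                                                2 * n)
    list(kd = kd, group = rep(c("HC", "pat"), each = n),
         age = rnorm(2 * n, 65, 8),
         gender = sample(c("M", "F"), 2 * n, replace = TRUE))
  }
  # type-I calibration
  ps <- vapply(1:400, function(r) {
    d <- simulate_kd(0, seed = r)
    rm_ancova_group(d$kd, d$group, d$age, d$gender)$p
  }, 0)
  rate <- mean(ps < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
  # power at a 1-SD offset with n = 30 per group
  power <- mean(vapply(1:100, function(r) {
    d <- simulate_kd(1, n = 30, seed = 1000 + r)
    rm_ancova_group(d$kd, d$group, d$age, d$gender)$p < 0.05
  }, TRUE))
  expect_gt(power, 0.9)
  # single density equals a standard one-way ANCOVA from lm()
  d <- simulate_kd(0.5, seed = 99)
  ours <- rm_ancova_group(d$kd[, 1, drop = FALSE], d$group, d$age, d$gender)
  dat <- data.frame(y = d$kd[, 1], g = factor(d$group), age = d$age,
                    gender = as.numeric(factor(d$gender)) - 1)
  ref <- anova(lm(y ~ age + gender + g, data = dat))
  expect_equal(ours$F, ref["g", "F value"], tolerance = 1e-9)
  expect_equal(ours$p, ref["g", "Pr(>F)"], tolerance = 1e-9)
  expect_equal(ours$df2, ref["Residuals", "Df"])
})
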