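test_that("normality screening behaves at both tails and rejects degenerate input", {
  expect_error(ks_normality(c(1, 1, 1)), "zero variance")
  expect_error(ks_normality(c(1, 2)), "at least 3")
  expect_error(ks_normality(c(1, 2, 3, 4)), "at least 5")
  # 4 distinct values are enough for the plain KS variant
  expect_type(ks_normality(c(1, 2, 3, 5), method = "ks")$p, "double")
  set.seed(61)
  x <- stats::rnorm(200, 50, 4)
  r <- ks_normality(x)
  expect_gt(r$p, 0.05)
  expect_true(r$statistic >= 0 && r$statistic <= 1)
  # power against a clearly skewed alternative
  rej <- vapply(1:60, function(k) {
    set.seed(1000 + k)
    ks_normality(stats::rexp(200))$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.95)
  # plain one-sample KS variant available and anti-conservative vs Lilliefors
  r2 <- ks_normality(x, method = "ks")
  expect_gte(r2$p, r$p)
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  # groups {1,2,3} and {4,5,6}: SSB = 13.5, SSW = 4, F = 13.5/(4/4) = 13.5
  r <- oneway_anova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(r$F, 13.5)
  expect_equal(unname(r$df), c(1, 4))
  # p from the F distribution, hand-checked magnitude
  expect_lt(abs(r$p - 0.02131164), 1e-7)
  expect_equal(r$tukey$diff, 3)
  expect_equal(r$tukey$p_adj, r$p, tolerance = 1e-4)  # 2 groups: HSD = F test
  # identical means: F = 0, p = 1
  r0 <- oneway_anova(c(1, 3, 1, 3, 1, 3), rep(c("a", "b", "c"), each = 2))
  expect_equal(r0$F, 0)
  expect_equal(r0$p, 1)
  # permutation of group labels leaves F and p unchanged
  set.seed(67)
  v <- stats::rnorm(12)
  gl <- rep(c("x", "y", "z"), each = 4)
  ra <- oneway_anova(v, gl)
  perm <- c(z = "a", x = "b", y = "c")[gl]
  rb <- oneway_anova(v, perm)
  expect_equal(ra$F, rb$F)
  expect_equal(ra$p, rb$p)
  expect_error(oneway_anova(c(1, 2, 3), c("a", "a", "b")), "at least 2")
})

test_that("ANOVA p-values are uniform under the null", {
  set.seed(71)
  ps <- vapply(1:400, function(k) {
    oneway_anova(stats::rnorm(9), rep(1:3, each = 3))$p
  }, numeric(1))
  d <- suppressWarnings(stats::ks.test(ps, "punif")$statistic)
  expect_lt(unname(d), 0.07)
})

test_that("percent agreement counts matching verdicts symmetrically", {
  tab <- rating_table(c("changed", "unchanged", "changed"),
                      c("changed", "unchanged", "changed"))
  expect_equal(percent_agreement(tab, "r1", "r2"), 100)
  tab2 <- rating_table(rep("changed", 4), rep("unchanged", 4))
  expect_equal(percent_agreement(tab2, "r1", "r2"), 0)
  set.seed(73)
  a <- sample(c("changed", "unchanged"), 10, replace = TRUE)
  b <- sample(c("changed", "unchanged"), 10, replace = TRUE)
  tab3 <- rating_table(a, b)
  expect_equal(percent_agreement(tab3, "r1", "r2"), 100 * sum(a == b) / 10)
  expect_equal(percent_agreement(tab3, "r1", "r2"),
               percent_agreement(tab3, "r2", "r1"))
  expect_error(percent_agreement(tab3, "r1", "r9"), "absent")
})

test_that("Cohen's kappa matches the direct formula and the reference headline configuration", {
  # perfect agreement with mixed marginals
  tab <- rating_table(c("c", "u", "c", "u"), c("c", "u", "c", "u"))
  expect_equal(cohens_kappa(tab, "r1", "r2")$kappa, 1)
  # statistically independent raters built as a product table:
  # a repeats each of its two values over b's full pattern
  a <- rep(c("c", "u"), each = 4)
  b <- rep(c("c", "c", "u", "u"), 2)
  expect_equal(cohens_kappa(rating_table(a, b), "r1", "r2")$kappa, 0)
  # 2x2 counts a=6, b=1, c=0, d=3: p_o = 0.9, p_e = 0.54,
  # kappa = 0.36/0.46 = 0.7826...; z-test p ~ 0.011
  a <- c(rep("changed", 7), rep("unchanged", 3))
  b <- c(rep("changed", 6), "unchanged", rep("unchanged", 3))
  k <- cohens_kappa(rating_table(a, b), "r1", "r2")
  expect_equal(k$kappa, 0.36 / 0.46, tolerance = 1e-12)
  expect_equal(k$p_o, 0.9)
  expect_equal(k$p_e, 0.54)
  expect_lt(abs(k$p - 0.011), 5e-4)
  # permutation p agrees in magnitude with the normal approximation
  kp <- cohens_kappa(rating_table(a, b), "r1", "r2", method = "permutation",
                     n_perm = 4000, seed = 2)
  expect_lt(abs(kp$p - k$p), 0.05)
  # cross-check the coefficient against an independent implementation
  ct <- table(a, b)
  expect_equal(k$kappa, e1071::classAgreement(ct)$kappa, tolerance = 1e-12)
})

test_that("kappa is undefined when both raters are constant and identical", {
  tab <- rating_table(rep("c", 5), rep("c", 5))
  k <- cohens_kappa(tab, "r1", "r2")
  expect_true(k$undefined)
  expect_true(is.nan(k$kappa))
})

test_that("model verdict binarization follows the ANOVA gate", {
  p <- strong_effect_params(seed = 79, n_subjects = 2)
  g <- generate_cohort(p)
  res <- run_pipeline(g$dataset, markers = "hip", load_pairs = list(c(0, 75)),
                      N_range = 2:6, M = 12, seed = 1)
  mv <- model_verdicts(res$reports, alpha = 0.05)
  expect_equal(nrow(mv), 2)
  expect_setequal(mv$verdict[res$summary$gated], "changed")
  # agreement machinery runs against a synthetic human rater
  set.seed(80)
  human <- data.frame(item = mv$item, rater = "eval1",
                      verdict = sample(c("changed", "unchanged"),
                                       nrow(mv), replace = TRUE))
  tab <- rbind(mv, human)
  pa <- percent_agreement(tab, "model", "eval1")
  expect_true(pa >= 0 && pa <= 100)
})
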