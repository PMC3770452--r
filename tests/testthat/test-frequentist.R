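test_that("pooled fit is the closed-form pooled proportion", {
  fit <- fit_pooled(gaba_table())
  expect_equal(as.numeric(fit$gamma), c(79, 125, 89) / 293)
  expect_equal(sum(fit$expected_case), 188)
  expect_equal(sum(fit$expected_control), 105)

  same <- fit_pooled(genotype_table(c(3, 5, 2), c(3, 5, 2)))
  expect_equal(as.numeric(same$gamma), c(3, 5, 2) / 10)

  bnd <- fit_pooled(genotype_table(c(1, 0, 0), c(0, 0, 1)))
  expect_equal(as.numeric(bnd$gamma), c(0.5, 0, 0.5))
  expect_true(bnd$boundary)
})

test_that("genotypic and usual allelic statistics match chisq.test", {
  gt <- gaba_table()
  g <- genotypic_test(gt)
  oracle_g <- suppressWarnings(chisq.test(as.matrix(gt), correct = FALSE))
  expect_equal(g$statistic, unname(oracle_g$statistic))
  expect_equal(g$p.value, oracle_g$p.value)

  u <- allelic_test_usual(gt)
  al <- allele_table(gt)
  oracle_u <- suppressWarnings(
    chisq.test(rbind(al$case, al$control), correct = FALSE))
  expect_equal(u$statistic, unname(oracle_u$statistic))
  expect_equal(u$p.value, oracle_u$p.value)
  expect_match(u$warning, "Hardy-Weinberg")

  # perfect homogeneity: statistic 0, p = 1, for both tests
  same <- genotype_table(c(6, 10, 4), c(6, 10, 4))
  expect_equal(genotypic_test(same)$statistic, 0)
  expect_equal(genotypic_test(same)$p.value, 1)
  expect_equal(allelic_test_usual(same)$p.value, 1)
})

test_that("trend test equals the independent implementation and errors when degenerate", {
  gt <- gaba_table()
  tr <- armitage_trend_test(gt)
  oracle <- prop.trend.test(as.numeric(gt$case),
                            as.numeric(gt$case) + as.numeric(gt$control),
                            score = c(2, 1, 0))
  expect_equal(tr$statistic, unname(oracle$statistic))
  expect_equal(tr$p.value, oracle$p.value)

  expect_equal(armitage_trend_test(genotype_table(c(4, 4, 4),
                                                  c(4, 4, 4)))$statistic, 0)
  expect_error(armitage_trend_test(genotype_table(c(0, 9, 0), c(0, 3, 0))),
               "undefined")
})

test_that("HWE goodness of fit behaves at equilibrium and rejects monomorphic input", {
  expect_equal(hwe_test(c(25, 50, 25))$statistic, 0)
  expect_equal(hwe_test(c(25, 50, 25))$p.value, 1)
  expect_error(hwe_test(c(10, 0, 0)), "monomorphic")
  # matches a direct goodness-of-fit computation
  v <- c(30, 40, 30); N <- 100; p <- (60 + 40) / 200
  expected <- N * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  expect_equal(hwe_test(v)$statistic, sum((v - expected)^2 / expected))
})

test_that("chi-square upper tail honours the quantile identities", {
  expect_equal(asymptotic_pvalue(0, 5), 1)
  expect_equal(asymptotic_pvalue(qchisq(0.95, 1), 1), 0.05)
  expect_equal(asymptotic_pvalue(qchisq(0.95, 2), 2), 0.05)
  expect_equal(asymptotic_pvalue(Inf, 1), 0)
})

test_that("MC engine is seeded, tie-inclusive, and its CI brackets the estimate", {
  gt <- gaba_table()
  fit <- fit_pooled(gt)
  stat_fn <- function(tab) genotypic_test(tab)$statistic

  a <- mc_exact_pvalue(gt, stat_fn, fit, n_reps = 500, seed = 42)
  b <- mc_exact_pvalue(gt, stat_fn, fit, n_reps = 500, seed = 42)
  expect_identical(a$p.value, b$p.value)
  expect_true(a$mc_ci[1] <= a$p.value && a$p.value <= a$mc_ci[2])

  # observed statistic 0: every replicate ties or exceeds
  same <- genotype_table(c(6, 10, 4), c(6, 10, 4))
  expect_equal(mc_exact_pvalue(same, stat_fn, fit_pooled(same),
                               n_reps = 200, seed = 1)$p.value, 1)
})

test_that("CI width shrinks like one over the square root of the replicate count", {
  gt <- gaba_table()
  fit <- fit_pooled(gt)
  stat_fn <- function(tab) genotypic_test(tab)$statistic
  w <- sapply(c(1000, 4000), function(B) {
    ci <- mc_exact_pvalue(gt, stat_fn, fit, n_reps = B, seed = 7)$mc_ci
    diff(ci)
  })
  expect_equal(w[1] / w[2], 2, tolerance = 0.2)
})
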