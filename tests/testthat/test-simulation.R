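test_that("table sampling is seeded and follows the generating model", {
  deg <- sample_table(c(1, 0, 0), c(0, 1, 0), n = 12, m = 7, seed = 1)
  expect_equal(as.numeric(deg$case), c(12, 0, 0))
  expect_equal(as.numeric(deg$control), c(0, 7, 0))

  a <- sample_table(c(0.2, 0.5, 0.3), c(0.3, 0.3, 0.4), 50, 50, seed = 4)
  b <- sample_table(c(0.2, 0.5, 0.3), c(0.3, 0.3, 0.4), 50, 50, seed = 4)
  expect_identical(as.matrix(a), as.matrix(b))

  # law of large numbers: empirical case frequencies within 3 SE
  g <- c(0.2, 0.5, 0.3)
  big <- sample_table(g, g, n = 10000, m = 1, seed = 6)
  se <- sqrt(g * (1 - g) / 10000)
  expect_true(all(abs(as.numeric(big$case) / 10000 - g) < 3 * se))
})

test_that("scenario construction places epsilon on the allele-frequency scale", {
  s1 <- build_scenario(1 / 5, 2 / 5, 1 / 4, 0)
  expect_equal(s1$pi[["AB"]], 0.3)
  s2 <- build_scenario(1 / 3, 1 / 5, 1 / 3, 0)
  expect_equal(s2$pi[["AB"]], 0.2)

  for (eps in c(0, 0.05, 0.1)) {
    s <- build_scenario(1 / 5, 2 / 5, 1 / 4, eps)
    diff_allele <- (s$gamma[["AA"]] + s$gamma[["AB"]] / 2) -
      (s$pi[["AA"]] + s$pi[["AB"]] / 2)
    expect_equal(unname(diff_allele), eps, tolerance = 1e-12)
  }
  expect_error(build_scenario(1 / 5, 2 / 5, 1 / 4, 0.9), "infeasible")
})

test_that("the three simulation regimes generate their strata", {
  set.seed(17)
  reg <- table6_regimes(margin = 0.05)
  for (i in 1:20) {
    r1 <- reg$genotypic_hom()
    expect_identical(r1$gamma, r1$pi)
    # genotypic homogeneity implies allelic homogeneity exactly
    expect_equal(r1$gamma[1] + r1$gamma[2] / 2, r1$pi[1] + r1$pi[2] / 2)

    r2 <- reg$allelic_hom_only()
    expect_equal(r2$gamma[1] + r2$gamma[2] / 2, r2$pi[1] + r2$pi[2] / 2,
                 tolerance = 1e-12)
    expect_false(isTRUE(all.equal(r2$gamma, r2$pi)))

    r3 <- reg$no_hom()
    expect_gte(abs((r3$gamma[1] + r3$gamma[2] / 2) -
                     (r3$pi[1] + r3$pi[2] / 2)), 0.05)
  }
})

test_that("power curve output is well-formed and reproducible", {
  pt <- power_curve(1 / 5, 2 / 5, 1 / 4, eps_grid = c(0, 0.1),
                    tests = c("usual_allelic", "corrected_allelic"),
                    n_datasets = 30, seed = 2)
  expect_s3_class(pt, "power_table")
  expect_equal(nrow(pt), 4)
  expect_true(all(pt$rate >= 0 & pt$rate <= 1))
  expect_true(all(pt$ci_lo <= pt$rate & pt$rate <= pt$ci_hi))
  expect_equal(pt$rate, pt$rejections / pt$n_datasets)

  pt2 <- power_curve(1 / 5, 2 / 5, 1 / 4, eps_grid = c(0, 0.1),
                     tests = c("usual_allelic", "corrected_allelic"),
                     n_datasets = 30, seed = 2)
  expect_identical(pt$rate, pt2$rate)
  expect_error(power_curve(1 / 5, 2 / 5, 1 / 4, eps_grid = numeric(0)),
               "empty")
})

test_that("power of the corrected test increases with epsilon", {
  pt <- power_curve(1 / 5, 2 / 5, 1 / 4, eps_grid = c(0, 0.15),
                    tests = "corrected_allelic", n_datasets = 150,
                    n = 100, m = 100, seed = 12)
  expect_gt(pt$rate[pt$epsilon == 0.15], pt$rate[pt$epsilon == 0] + 0.2)
})

test_that("coherence audit flags the published incoherence and never an e-violation", {
  rep1 <- coherence_audit(list(gaba_table()), alpha = 0.10,
                          n_draws = 5000, seed = 3)
  row <- rep1$results
  expect_true(row$p_incoherent_usual)
  expect_true(row$p_incoherent_corrected)
  expect_false(row$e_violation)

  # identical rows: all p-values 1, no flags possible
  same <- coherence_audit(list(genotype_table(c(6, 10, 4), c(6, 10, 4))),
                          alpha = 0.10, n_draws = 2000, seed = 4)
  expect_equal(same$results$p_genotypic, 1)
  expect_equal(same$results$p_corrected_allelic, 1, tolerance = 1e-6)
  expect_equal(same$n_p_incoherent, 0)
  expect_equal(same$n_e_violations, 0)

  # a batch of random tables: e-monotonicity violations are structurally zero
  batch <- coherence_audit(random_tables(20, seed = 8), alpha = 0.05,
                           n_draws = 1000, seed = 9)
  expect_equal(batch$n_e_violations, 0)
})
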