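test_that("posterior shapes are prior plus counts, exactly", {
  gt <- gaba_table()
  post <- posterior_from_counts(gt)
  expect_equal(as.numeric(post$alpha_case), c(56, 84, 51))
  expect_equal(as.numeric(post$alpha_control), c(25, 43, 40))

  pr <- dirichlet_prior(c(2, 0.5, 3), c(1, 1, 4))
  for (tab in random_tables(10, seed = 21)) {
    p <- posterior_from_counts(tab, pr)
    expect_equal(as.numeric(p$alpha_case) - as.numeric(pr$a),
                 as.numeric(tab$case))
    expect_equal(as.numeric(p$alpha_control) - as.numeric(pr$b),
                 as.numeric(tab$control))
  }
})

test_that("log posterior density is flat for all-ones shapes and matches a Dirichlet pdf", {
  # all-ones shapes => exponents all 0 => density identically 0
  flat <- structure(list(alpha_case = rep(1, 3), alpha_control = rep(1, 3)),
                    class = "dirichlet_posterior")
  set.seed(1)
  for (i in 1:5) {
    g <- rgamma(3, 1); g <- g / sum(g)
    p <- rgamma(3, 1); p <- p / sum(p)
    expect_equal(log_posterior_density(flat, g, p), 0)
  }

  # matches an independent Dirichlet log-pdf up to one additive constant
  post <- posterior_from_counts(gaba_table())
  ldirich <- function(t, a) sum((a - 1) * log(t)) +
    lgamma(sum(a)) - sum(lgamma(a))
  set.seed(2)
  diffs <- replicate(20, {
    g <- rgamma(3, 2); g <- g / sum(g)
    p <- rgamma(3, 2); p <- p / sum(p)
    log_posterior_density(post, g, p) -
      (ldirich(g, as.numeric(post$alpha_case)) +
         ldirich(p, as.numeric(post$alpha_control)))
  })
  expect_lt(diff(range(diffs)), 1e-9)

  # the componentwise mode dominates random draws
  mode_g <- (as.numeric(post$alpha_case) - 1) /
    sum(as.numeric(post$alpha_case) - 1)
  mode_p <- (as.numeric(post$alpha_control) - 1) /
    sum(as.numeric(post$alpha_control) - 1)
  at_mode <- log_posterior_density(post, mode_g, mode_p)
  set.seed(3)
  for (i in 1:100) {
    g <- rgamma(3, 1); g <- g / sum(g)
    p <- rgamma(3, 1); p <- p / sum(p)
    expect_gte(at_mode, log_posterior_density(post, g, p))
  }
})

test_that("null suprema: closed forms and grid oracles agree", {
  gt <- gaba_table()
  post <- posterior_from_counts(gt)

  # genotypic: pooled-exponent closed form equals the frequentist pooled MLE
  sg <- sup_under_null(post, "genotypic")
  expect_equal(as.numeric(sg$arg_sup$gamma), c(79, 125, 89) / 293)

  # allelic: when the unconstrained mode satisfies the constraint it is the sup
  tab0 <- genotype_table(c(10, 20, 10), c(5, 10, 5))
  sa0 <- sup_under_null(posterior_from_counts(tab0), "allelic")
  expect_equal(as.numeric(sa0$arg_sup$gamma), c(10, 20, 10) / 40,
               tolerance = 1e-5)

  # allelic sup is never below the genotypic sup (nesting)
  sa <- sup_under_null(post, "allelic")
  expect_gte(sa$sup_log_density, sg$sup_log_density)

  # HWE: closed form matches a fine 1-D grid search
  for (grp in c("hwe_case", "hwe_control")) {
    sh <- sup_under_null(post, grp)
    e <- if (grp == "hwe_case") c(55, 83, 50) else c(24, 42, 39)
    pg <- seq(1e-5, 1 - 1e-5, by = 1e-5)
    vals <- e[1] * 2 * log(pg) + e[2] * log(2 * pg * (1 - pg)) +
      e[3] * 2 * log(1 - pg)
    expect_gte(sh$sup_log_density + 1e-8, max(vals))
    expect_equal(sh$arg_sup$p, pg[which.max(vals)], tolerance = 1e-4)
  }
})

test_that("e-values are seeded, bounded, and hit 1 for a saturated null", {
  gt <- gaba_table()
  a <- evalue(gt, "genotypic", n_draws = 2000, seed = 10)
  b <- evalue(gt, "genotypic", n_draws = 2000, seed = 10)
  expect_identical(a$evalue, b$evalue)
  expect_true(a$evalue >= 0 && a$evalue <= 1)
  expect_lte(a$mc_se, 0.5 / sqrt(2000))

  # when the null contains the posterior mode the tangential set is empty
  tab0 <- genotype_table(c(10, 20, 10), c(5, 10, 5))
  expect_equal(evalue(tab0, "allelic", n_draws = 2000, seed = 1)$evalue, 1)
})

test_that("shared-draw monotonicity holds on every random table", {
  for (tab in random_tables(40, seed = 31)) {
    ev <- evalue_pair(tab, n_draws = 1000, seed = 5)
    expect_lte(ev$genotypic$evalue, ev$allelic$evalue)
  }
})

test_that("cutoff calibration reproduces the chi-square link", {
  # frozen from the closed form 1 - F_d(F^-1_{d-h}(1 - alpha))
  expect_equal(evalue_cutoff(0.05, 4, 3)$cutoff, 0.42788705,
               tolerance = 1e-7)
  expect_equal(evalue_cutoff(0.05, 4, 2)$cutoff, 0.19978661,
               tolerance = 1e-7)
  # limits: vanishing level keeps everything, level near 1 rejects all
  expect_lt(evalue_cutoff(1e-6, 4, 3)$cutoff, 1e-3)
  expect_gt(evalue_cutoff(1 - 1e-9, 4, 3)$cutoff, 1 - 1e-6)
  # monotone increasing in alpha (higher level rejects more easily)
  al <- seq(0.01, 0.5, by = 0.05)
  cuts <- sapply(al, function(a) evalue_cutoff(a, 4, 2)$cutoff)
  expect_true(all(diff(cuts) > 0))
  expect_error(evalue_cutoff(0.05, 2, 2))
})

test_that("genotypic Bayes factor closed form matches Monte-Carlo integration", {
  tab <- genotype_table(c(2, 2, 1), c(1, 3, 1))
  bf <- bayes_factor(tab, "genotypic")
  # brute-force MC: uniform draws on each simplex / common simplex
  set.seed(99)
  M <- 200000
  kern <- function(t, cnt) exp(colSums(cnt * log(t)))
  rsimp <- function(k) { g <- matrix(rgamma(3 * k, 1), 3); t(t(g) / colSums(g)) }
  g <- rsimp(M); p <- rsimp(M); q <- rsimp(M)
  num <- mean(kern(q, as.numeric(tab$case) + as.numeric(tab$control)))
  den <- mean(kern(g, as.numeric(tab$case))) *
    mean(kern(p, as.numeric(tab$control)))
  mc_bf <- num / den
  expect_equal(bf$bf, mc_bf, tolerance = 0.05)

  # allelic BF runs, is positive, and is seed-reproducible
  b1 <- bayes_factor(gaba_table(), "allelic", n_draws = 50000, seed = 8)
  b2 <- bayes_factor(gaba_table(), "allelic", n_draws = 50000, seed = 8)
  expect_identical(b1$bf, b2$bf)
  expect_gt(b1$bf, 0)
})
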