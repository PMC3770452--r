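# Chi-square homogeneity tests, HWE goodness of fit, Cochran-Armitage
# trend, and the Monte-Carlo (parametric bootstrap) exact p-value engine.

# Pearson sum with the zero-cell conventions used throughout: an expected 0
# with observed 0 contributes 0; expected 0 with observed > 0 yields +Inf.
pearson_sum <- function(obs, exp) {
  obs <- unname(obs)
  exp <- unname(exp)
  out <- 0
  for (i in seq_along(obs)) {
    if (exp[i] > 0) {
      out <- out + (obs[i] - exp[i])^2 / exp[i]
    } else if (obs[i] > 0) {
      return(Inf)
    }
  }
  out
}

#' Upper-tail chi-square p-value
#'
#' @param statistic non-negative test statistic (may be `Inf`).
#' @param df degrees of freedom.
#' @return `P(Chi^2_df >= statistic)`.
#' @export
asymptotic_pvalue <- function(statistic, df) {
  stopifnot(statistic >= 0, df >= 1)
  stats::pchisq(statistic, df = df, lower.tail = FALSE)
}

new_homog_test <- function(statistic, df, p, method, test, n_reps = NULL,
                           mc_ci = NULL, seed = NULL, warning = NULL,
                           fit = NULL) {
  structure(
    list(statistic = statistic, df = df, p.value = p, method = method,
         test = test, n_reps = n_reps, mc_ci = mc_ci, seed = seed,
         warning = warning, fit = fit),
    class = "homog_test")
}

#' @export
print.homog_test <- function(x, digits = 4, ...) {
  cat(x$test, "\n")
  cat(sprintf("  statistic = %s, df = %d, p-value = %s (%s)\n",
              format(x$statistic, digits = digits), x$df,
              format(x$p.value, digits = digits), x$method))
  if (identical(x$method, "monte_carlo")) {
    cat(sprintf("  %d replicates, 95%% CI [%s, %s], seed %s\n",
                x$n_reps, format(x$mc_ci[1], digits = digits),
                format(x$mc_ci[2], digits = digits),
                format(x$seed)))
  }
  if (!is.null(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

#' Chi-square test of genotypic homogeneity
#'
#' Tests whether the case and control genotype frequency vectors coincide,
#' via the Pearson statistic on the 2x3 table with expected counts from the
#' pooled MLE. Asymptotically chi-square with 2 degrees of freedom under the
#' null; a Monte-Carlo exact p-value is available by parametric bootstrap
#' from the pooled fit (both groups resampled as independent multinomials).
#'
#' @param x a [genotype_table()].
#' @param method `"asymptotic"` (default) or `"mc"` for the parametric
#'   bootstrap exact p-value.
#' @param n_reps bootstrap replicates for `method = "mc"`.
#' @param seed RNG seed for `method = "mc"`; recorded in the result.
#' @return A `homog_test` object: `statistic`, `df`, `p.value`, `method`,
#'   and for Monte-Carlo runs `n_reps`, `mc_ci` (95% normal-approximation
#'   interval) and `seed`.
#' @examples
#' gt <- genotype_table(c(55, 83, 50), c(24, 42, 39))
#' genotypic_test(gt)
#' @export
genotypic_test <- function(x, method = c("asymptotic", "mc"),
                           n_reps = 10000, seed = NULL) {
  stopifnot(inherits(x, "genotype_table"))
  method <- match.arg(method)
  fit <- fit_pooled(x)
  stat_fn <- function(tab) {
    f <- fit_pooled(tab)
    pearson_sum(as.numeric(tab$case), f$expected_case) +
      pearson_sum(as.numeric(tab$control), f$expected_control)
  }
  q <- stat_fn(x)
  if (method == "asymptotic") {
    new_homog_test(q, 2L, asymptotic_pvalue(q, 2L), "asymptotic",
                   "Genotypic homogeneity chi-square test", fit = fit)
  } else {
    mc <- mc_exact_pvalue(x, stat_fn, fit, n_reps = n_reps, seed = seed)
    new_homog_test(q, 2L, mc$p.value, "monte_carlo",
                   "Genotypic homogeneity test (parametric bootstrap)",
                   n_reps = mc$n_reps, mc_ci = mc$mc_ci, seed = mc$seed,
                   fit = fit)
  }
}

#' Traditional doubled-sample allelic test (biased without HWE)
#'
#' The textbook allelic test: collapse the genotype table to the 2x2 allele
#' table (two alleles per individual, so twice the sample size) and apply
#' the Pearson chi-square test of homogeneity with 1 degree of freedom.
#' This treats alleles as independent observations, which is justified if
#' and only if both groups are in Hardy-Weinberg equilibrium; otherwise the
#' true size differs from the nominal level. The test is provided as the
#' comparator whose bias the corrected test removes, and every result
#' carries the validity warning.
#'
#' @inheritParams genotypic_test
#' @return A `homog_test` object; `$warning` states the HWE validity caveat.
#' @examples
#' gt <- genotype_table(c(55, 83, 50), c(24, 42, 39))
#' allelic_test_usual(gt)
#' @export
allelic_test_usual <- function(x, method = c("asymptotic", "mc"),
                               n_reps = 10000, seed = NULL) {
  stopifnot(inherits(x, "genotype_table"))
  method <- match.arg(method)
  stat_fn <- function(tab) {
    al <- allele_table(tab)
    lam <- (as.numeric(al$case) + as.numeric(al$control)) /
      (al$two_n + al$two_m)
    pearson_sum(as.numeric(al$case), al$two_n * lam) +
      pearson_sum(as.numeric(al$control), al$two_m * lam)
  }
  q <- stat_fn(x)
  warn <- paste("valid only if both groups are in Hardy-Weinberg",
                "equilibrium; see allelic_test_corrected()")
  if (method == "asymptotic") {
    new_homog_test(q, 1L, asymptotic_pvalue(q, 1L), "asymptotic",
                   "Usual (doubled-sample) allelic chi-square test",
                   warning = warn)
  } else {
    # Bootstrap under the product-multinomial model at the constrained MLE
    # of the genotype-level allelic null (the model the data actually follow).
    fit <- fit_allelic_null(x)
    mc <- mc_exact_pvalue(x, stat_fn, fit, n_reps = n_reps, seed = seed)
    new_homog_test(q, 1L, mc$p.value, "monte_carlo",
                   "Usual allelic test (parametric bootstrap)",
                   n_reps = mc$n_reps, mc_ci = mc$mc_ci, seed = mc$seed,
                   warning = warn)
  }
}

#' Corrected allelic homogeneity test (valid without HWE)
#'
#' Tests equality of allele frequencies while staying in the genotype-level
#' product-multinomial model, so no Hardy-Weinberg assumption is needed.
#' The null states that `gamma_AA + gamma_AB/2 = Pi_AA + Pi_AB/2`; expected
#' counts come from the constrained MLE ([fit_allelic_null()]) and the
#' Pearson statistic over all six genotype cells has 1 degree of freedom
#' (the ambient parameter space has dimension 4, the null set dimension 3).
#'
#' With `method = "mc"` (the recommended, exact form) the null distribution
#' is simulated by parametric bootstrap: case and control tables are drawn
#' from multinomials at the constrained MLE, the constrained fit is
#' recomputed on every replicate, and the p-value is the proportion of
#' replicate statistics at least as large as the observed one (ties count
#' as exceedances).
#'
#' @inheritParams genotypic_test
#' @param x a [genotype_table()].
#' @return A `homog_test` object; `$fit` holds the constrained null fit.
#' @examples
#' gt <- genotype_table(c(55, 83, 50), c(24, 42, 39))
#' allelic_test_corrected(gt)                       # asymptotic
#' allelic_test_corrected(gt, "mc", 2000, seed = 1) # bootstrap (small run)
#' @export
allelic_test_corrected <- function(x, method = c("asymptotic", "mc"),
                                   n_reps = 10000, seed = NULL) {
  stopifnot(inherits(x, "genotype_table"))
  method <- match.arg(method)
  fit <- fit_allelic_null(x)
  # statistics below the optimiser's resolution are exact zeros (the null
  # fits the table perfectly); snapping keeps bootstrap ties well-defined
  stat_fn <- function(tab) {
    f <- fit_allelic_null(tab)
    q <- pearson_sum(as.numeric(tab$case), f$expected_case) +
      pearson_sum(as.numeric(tab$control), f$expected_control)
    if (q < 1e-9) 0 else q
  }
  q <- stat_fn(x)
  if (method == "asymptotic") {
    new_homog_test(q, 1L, asymptotic_pvalue(q, 1L), "asymptotic",
                   "Corrected allelic homogeneity test", fit = fit)
  } else {
    mc <- mc_exact_pvalue(x, stat_fn, fit, n_reps = n_reps, seed = seed)
    new_homog_test(q, 1L, mc$p.value, "monte_carlo",
                   "Corrected allelic homogeneity test (parametric bootstrap)",
                   n_reps = mc$n_reps, mc_ci = mc$mc_ci, seed = mc$seed,
                   fit = fit)
  }
}

#' Cochran-Armitage trend test
#'
#' The 1-df trend test on the 2x3 genotype table with allele-dosage scores
#' 0, 1, 2 on BB, AB, AA. Asymptotically equivalent to the corrected
#' allelic test, and used here as its cross-check.
#'
#' @param x a [genotype_table()].
#' @return A `homog_test` object with the trend statistic and asymptotic
#'   1-df p-value.
#' @export
armitage_trend_test <- function(x) {
  stopifnot(inherits(x, "genotype_table"))
  s <- c(2, 1, 0)  # A-allele dosage on AA, AB, BB (orientation immaterial)
  cx <- as.numeric(x$case)
  cy <- as.numeric(x$control)
  tot <- cx + cy
  N <- x$n + x$m
  sbar <- sum(s * tot) / N
  denom <- x$n * x$m / N^2 * (N * sum(s^2 * tot) - sum(s * tot)^2) / N
  if (denom <= 0) {
    stop("trend statistic undefined: all individuals share one genotype",
         call. = FALSE)
  }
  num <- sum(s * (cx - x$n * tot / N))
  stat <- num^2 / denom
  new_homog_test(stat, 1L, asymptotic_pvalue(stat, 1L), "asymptotic",
                 "Cochran-Armitage trend test (scores 0,1,2)")
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' Standard 1-df chi-square goodness-of-fit for one group's genotype counts
#' against the Hardy-Weinberg expectations `N p^2, 2 N p (1-p), N (1-p)^2`
#' with `p` estimated as the sample allele-A frequency. No continuity
#' correction.
#'
#' @param counts genotype count 3-vector (AA, AB, BB) for one group, or a
#'   [genotype_table()] together with `group`.
#' @param group `"case"` or `"control"`, used when `counts` is a
#'   `genotype_table`.
#' @return A `homog_test` object.
#' @examples
#' hwe_test(c(55, 83, 50))
#' @export
hwe_test <- function(counts, group = c("case", "control")) {
  if (inherits(counts, "genotype_table")) {
    group <- match.arg(group)
    counts <- counts[[group]]
  }
  counts <- check_counts3(counts, "group")
  N <- sum(counts)
  if (N < 1) stop("empty group", call. = FALSE)
  p <- (2 * counts[["AA"]] + counts[["AB"]]) / (2 * N)
  if (p <= 0 || p >= 1) {
    stop("HWE test undefined for a monomorphic sample (allele frequency ",
         format(p), ")", call. = FALSE)
  }
  expc <- N * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  stat <- pearson_sum(as.numeric(counts), expc)
  new_homog_test(stat, 1L, asymptotic_pvalue(stat, 1L), "asymptotic",
                 "Hardy-Weinberg equilibrium goodness-of-fit test")
}

#' Monte-Carlo exact p-value by parametric bootstrap
#'
#' Simulates the null distribution of an arbitrary table statistic: case
#' and control rows are drawn as independent multinomials at the fitted
#' null frequencies, the statistic is recomputed on every replicate, and
#' the p-value is the proportion of replicates with statistic greater than
#' or equal to the observed value. A 95% normal-approximation binomial
#' interval quantifies the Monte-Carlo error.
#'
#' @param x a [genotype_table()] (the observed data).
#' @param statistic function taking a `genotype_table` and returning a
#'   scalar statistic (larger = more extreme).
#' @param null_fit a `fitted_null` supplying the generating frequencies
#'   `gamma` and `pi`.
#' @param n_reps number of bootstrap replicates (>= 100).
#' @param seed RNG seed; drawn at random (and still recorded) when `NULL`.
#' @return List with `p.value`, `n_reps`, `mc_ci`, `seed`, `observed`, and
#'   `n_failed` (replicates whose statistic evaluation failed; more than 1%
#'   failures aborts).
#' @export
mc_exact_pvalue <- function(x, statistic, null_fit, n_reps = 10000,
                            seed = NULL) {
  stopifnot(inherits(x, "genotype_table"), is.function(statistic),
            inherits(null_fit, "fitted_null"), n_reps >= 100)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  obs <- statistic(x)
  gamma <- as.numeric(null_fit$gamma)
  pi <- as.numeric(null_fit$pi)
  exceed <- 0L
  failed <- 0L
  with_seed(seed, {
    cases <- stats::rmultinom(n_reps, x$n, gamma)
    ctrls <- stats::rmultinom(n_reps, x$m, pi)
    for (b in seq_len(n_reps)) {
      tab <- genotype_table(cases[, b], ctrls[, b])
      sb <- tryCatch(statistic(tab), error = function(e) NA_real_)
      if (is.na(sb)) {
        failed <- failed + 1L
      } else if (sb >= obs) {
        exceed <- exceed + 1L
      }
    }
  })
  if (failed > 0.01 * n_reps) {
    stop(sprintf("statistic failed on %d of %d bootstrap replicates",
                 failed, n_reps), call. = FALSE)
  }
  used <- n_reps - failed
  p <- exceed / used
  half <- 1.96 * sqrt(p * (1 - p) / used)
  list(p.value = p, n_reps = used,
       mc_ci = c(max(0, p - half), min(1, p + half)),
       seed = seed, observed = obs, n_failed = failed)
}

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
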