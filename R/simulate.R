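# Seeded simulation of product-multinomial genotype tables, scenario
# construction on and off the allelic null, size/power estimation, and the
# coherence auditor.

#' Draw a genotype table from the product-multinomial model
#'
#' @param gamma genotype frequency 3-vector for the case group.
#' @param pi genotype frequency 3-vector for the control group.
#' @param n,m group sizes.
#' @param seed RNG seed (optional; caller's stream used when `NULL`).
#' @return A [genotype_table()].
#' @export
sample_table <- function(gamma, pi, n, m, seed = NULL) {
  gamma <- check_prob3(gamma, "gamma")
  pi <- check_prob3(pi, "pi")
  stopifnot(n >= 1, m >= 1)
  draw <- function() {
    genotype_table(as.vector(stats::rmultinom(1, n, gamma)),
                   as.vector(stats::rmultinom(1, m, pi)))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Build a power-study scenario at a given distance from allelic homogeneity
#'
#' Fixes `gamma_AA`, `gamma_AB` and `Pi_AA`, and sets
#' `Pi_AB = 2 (gamma_AA + gamma_AB / 2 - Pi_AA - epsilon)`,
#' so that `epsilon` is exactly the difference in allele-A frequency
#' between the groups: `epsilon = 0` puts the scenario on the allelic null,
#' with no Hardy-Weinberg assumption anywhere.
#'
#' @param gamma_AA,gamma_AB case-group AA and AB frequencies.
#' @param pi_AA control-group AA frequency.
#' @param epsilon departure from allelic homogeneity (allele-frequency
#'   difference, case minus control).
#' @param n,m group sizes (default 100 each, the scale of the package's
#'   power studies).
#' @return An object of class `power_scenario` with `gamma`, `pi`,
#'   `epsilon`, `n`, `m`.
#' @examples
#' build_scenario(1/5, 2/5, 1/4, 0)   # Pi_AB = 0.3, null holds
#' build_scenario(1/3, 1/5, 1/3, 0)   # Pi_AB = 0.2, null holds
#' @export
build_scenario <- function(gamma_AA, gamma_AB, pi_AA, epsilon = 0,
                           n = 100, m = 100) {
  gamma <- c(gamma_AA, gamma_AB, 1 - gamma_AA - gamma_AB)
  pi_AB <- 2 * (gamma_AA + gamma_AB / 2 - pi_AA - epsilon)
  pi <- c(pi_AA, pi_AB, 1 - pi_AA - pi_AB)
  freqs <- c(gamma, pi)
  names(freqs) <- c(paste0("gamma_", GENO), paste0("Pi_", GENO))
  bad <- which(freqs < -1e-12 | freqs > 1 + 1e-12)
  if (length(bad)) {
    stop(sprintf(
      "epsilon = %s is infeasible: %s = %s lies outside [0, 1]",
      format(epsilon), names(freqs)[bad[1]], format(freqs[bad[1]])),
      call. = FALSE)
  }
  structure(list(gamma = check_prob3(gamma, "gamma"),
                 pi = check_prob3(pi, "pi"),
                 epsilon = epsilon, n = n, m = m),
            class = "power_scenario")
}

#' Generators for the three simulation regimes
#'
#' Returns three seeded generator functions producing random genotype
#' frequency pairs `(gamma, pi)`:
#' 1. `genotypic_hom`: `gamma = pi` (both homogeneities hold);
#' 2. `allelic_hom_only`: equal allele frequencies but `gamma != pi`;
#' 3. `no_hom`: allele frequencies differ by at least `margin`.
#' Frequencies are drawn uniformly on the simplex (regime 2 additionally
#' resamples the control heterozygote split at the shared allele
#' frequency), so each regime covers its stratum rather than a single
#' point.
#'
#' @param margin minimum allele-frequency difference enforced in regime 3.
#' @return Named list of functions, each taking nothing and returning
#'   `list(gamma, pi)` using the caller's RNG stream.
#' @export
table6_regimes <- function(margin = 0.05) {
  runif_simplex <- function() {
    g <- stats::rgamma(3, 1)
    g / sum(g)
  }
  list(
    genotypic_hom = function() {
      g <- runif_simplex()
      list(gamma = g, pi = g)
    },
    allelic_hom_only = function() {
      repeat {
        g <- runif_simplex()
        lam <- g[1] + g[2] / 2
        tmax <- 2 * min(lam, 1 - lam)
        if (tmax <= 0) next
        t <- stats::runif(1, 0, tmax)
        p <- c(lam - t / 2, t, 1 - lam - t / 2)
        if (max(abs(p - g)) > 1e-6) return(list(gamma = g, pi = p))
      }
    },
    no_hom = function() {
      repeat {
        g <- runif_simplex()
        p <- runif_simplex()
        if (abs((g[1] + g[2] / 2) - (p[1] + p[2] / 2)) >= margin) {
          return(list(gamma = g, pi = p))
        }
      }
    })
}

# Available reject/accept criteria for the allelic (and genotypic) nulls.
power_tests <- function(alpha, mc_reps, fbst_draws) {
  cut_a <- evalue_cutoff(alpha, 4, 3)$cutoff
  cut_g <- evalue_cutoff(alpha, 4, 2)$cutoff
  list(
    usual_allelic = function(tab, seed)
      allelic_test_usual(tab)$p.value <= alpha,
    corrected_allelic = function(tab, seed)
      allelic_test_corrected(tab)$p.value <= alpha,
    corrected_allelic_mc = function(tab, seed)
      allelic_test_corrected(tab, "mc", n_reps = mc_reps,
                             seed = seed)$p.value <= alpha,
    fbst_allelic = function(tab, seed)
      evalue(tab, "allelic", n_draws = fbst_draws,
             seed = seed)$evalue <= cut_a,
    genotypic = function(tab, seed)
      genotypic_test(tab)$p.value <= alpha,
    fbst_genotypic = function(tab, seed)
      evalue(tab, "genotypic", n_draws = fbst_draws,
             seed = seed)$evalue <= cut_g)
}

#' Rejection-rate (size and power) estimation over an epsilon grid
#'
#' Simulates datasets from [build_scenario()] scenarios over a grid of
#' allele-frequency departures `epsilon` and estimates, for each requested
#' test, the proportion of datasets in which allelic homogeneity is
#' rejected at level `alpha`. At `epsilon = 0` the rate is the empirical
#' size of the test; elsewhere it is power. FBST tests reject when the
#' e-value falls at or below the chi-square calibration cutoff
#' ([evalue_cutoff()]).
#'
#' A master `seed` spawns an independent substream per dataset, so any
#' single dataset can be regenerated from (seed, epsilon index, dataset
#' index) alone.
#'
#' @param gamma_AA,gamma_AB,pi_AA scenario frequencies (see
#'   [build_scenario()]).
#' @param eps_grid vector of epsilon values; infeasible values are an error.
#' @param tests character subset of `"usual_allelic"`,
#'   `"corrected_allelic"` (asymptotic), `"corrected_allelic_mc"`,
#'   `"fbst_allelic"`, `"genotypic"`, `"fbst_genotypic"`.
#' @param alpha significance level.
#' @param n_datasets simulated datasets per grid point (100 mirrors a
#'   routine study; use >= 2000 for calibration checks).
#' @param n,m group sizes.
#' @param seed master seed.
#' @param mc_reps bootstrap replicates for `"corrected_allelic_mc"`.
#' @param fbst_draws posterior draws per dataset for the FBST tests.
#' @return A data.frame of class `power_table`: `epsilon`, `test`,
#'   `alpha`, `rejections`, `n_datasets`, `rate` and 95% binomial
#'   confidence bounds `ci_lo`, `ci_hi`.
#' @export
power_curve <- function(gamma_AA, gamma_AB, pi_AA,
                        eps_grid = seq(0, 0.2, by = 0.02),
                        tests = c("usual_allelic", "corrected_allelic",
                                  "fbst_allelic"),
                        alpha = 0.05, n_datasets = 100, n = 100, m = 100,
                        seed = 1, mc_reps = 1000, fbst_draws = 5000) {
  if (!length(eps_grid)) stop("eps_grid is empty", call. = FALSE)
  all_tests <- power_tests(alpha, mc_reps, fbst_draws)
  tests <- match.arg(tests, names(all_tests), several.ok = TRUE)
  rows <- list()
  for (k in seq_along(eps_grid)) {
    sc <- build_scenario(gamma_AA, gamma_AB, pi_AA, eps_grid[k], n, m)
    sub_seeds <- with_seed(seed + k, sample.int(2^31 - 2, n_datasets))
    rej <- stats::setNames(integer(length(tests)), tests)
    fail <- stats::setNames(integer(length(tests)), tests)
    for (i in seq_len(n_datasets)) {
      tab <- sample_table(sc$gamma, sc$pi, n, m, seed = sub_seeds[i])
      for (te in tests) {
        hit <- tryCatch(all_tests[[te]](tab, sub_seeds[i] %% (2^31 - 3) + 1),
                        error = function(e) NA)
        if (is.na(hit)) fail[te] <- fail[te] + 1L
        else if (hit) rej[te] <- rej[te] + 1L
      }
    }
    if (any(fail > 0.01 * n_datasets)) {
      stop("test failures exceeded 1% of datasets: ",
           paste(names(fail)[fail > 0.01 * n_datasets], collapse = ", "),
           call. = FALSE)
    }
    used <- n_datasets - fail
    rate <- rej / used
    half <- 1.96 * sqrt(rate * (1 - rate) / used)
    rows[[k]] <- data.frame(
      epsilon = eps_grid[k], test = tests, alpha = alpha,
      rejections = as.integer(rej), n_datasets = as.integer(used),
      rate = as.numeric(rate),
      ci_lo = pmax(0, rate - half), ci_hi = pmin(1, rate + half),
      row.names = NULL)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("power_table", "data.frame")
  attr(out, "scenario") <- list(gamma_AA = gamma_AA, gamma_AB = gamma_AB,
                                pi_AA = pi_AA, n = n, m = m, seed = seed)
  out
}

#' Coherence audit of p-values and e-values over a batch of tables
#'
#' For each table computes the five headline quantities -- genotypic
#' p-value, usual allelic p-value, corrected allelic p-value, and the
#' genotypic and allelic e-values (shared posterior draws) -- and flags
#' every level-`alpha` p-value incoherence: an allelic test rejecting while
#' the genotypic test accepts, which is logically impossible for the nested
#' hypotheses. E-value monotonicity violations (`e_G > e_A`) are counted
#' and must be zero by construction of the shared-draw computation.
#'
#' @param tables list of [genotype_table()] objects.
#' @param alpha significance level for the incoherence flags.
#' @param method p-value method for the allelic tests: `"asymptotic"`
#'   (default, fast) or `"mc"`.
#' @param n_reps bootstrap replicates when `method = "mc"`.
#' @param n_draws shared posterior draws per table.
#' @param seed master seed (one substream per table).
#' @return An object of class `audit_report`: data.frame `results` (one
#'   row per table with all five statistics and flags) plus summary counts.
#' @export
coherence_audit <- function(tables, alpha = 0.05,
                            method = c("asymptotic", "mc"),
                            n_reps = 10000, n_draws = 10000, seed = 1) {
  stopifnot(length(tables) >= 1)
  method <- match.arg(method)
  sub_seeds <- with_seed(seed, sample.int(2^31 - 2, length(tables)))
  rows <- lapply(seq_along(tables), function(i) {
    tab <- tables[[i]]
    stopifnot(inherits(tab, "genotype_table"))
    p_g <- genotypic_test(tab)$p.value
    p_u <- allelic_test_usual(tab)$p.value
    p_a <- allelic_test_corrected(tab, method, n_reps = n_reps,
                                  seed = sub_seeds[i])$p.value
    ev <- evalue_pair(tab, n_draws = max(n_draws, 1000),
                      seed = sub_seeds[i])
    data.frame(
      table = i, p_genotypic = p_g, p_usual_allelic = p_u,
      p_corrected_allelic = p_a,
      e_genotypic = ev$genotypic$evalue, e_allelic = ev$allelic$evalue,
      p_incoherent_usual = p_u <= alpha && p_g > alpha,
      p_incoherent_corrected = p_a <= alpha && p_g > alpha,
      e_violation = ev$genotypic$evalue > ev$allelic$evalue,
      seed = sub_seeds[i])
  })
  res <- do.call(rbind, rows)
  structure(
    list(results = res, alpha = alpha,
         n_p_incoherent = sum(res$p_incoherent_usual |
                                res$p_incoherent_corrected),
         n_e_violations = sum(res$e_violation),
         seed = seed),
    class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat(sprintf("Coherence audit of %d table(s) at alpha = %s\n",
              nrow(x$results), format(x$alpha)))
  cat(sprintf("  p-value incoherences: %d\n", x$n_p_incoherent))
  cat(sprintf("  e-value monotonicity violations: %d\n", x$n_e_violations))
  invisible(x)
}
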