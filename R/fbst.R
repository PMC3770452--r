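# Full Bayesian Significance Test for the nested homogeneity hypotheses.
#
# Model: independent Dirichlet priors on the two genotype frequency vectors
# are conjugate to the product-multinomial likelihood, so the posterior is
# again a product of Dirichlets with shapes (counts + prior). The e-value of
# a sharp hypothesis is one minus the posterior probability of the
# tangential set, the set of parameter points whose posterior density
# strictly exceeds the supremum attained on the null set. All density
# comparisons use one fixed unnormalised log scale (sum of (shape - 1) *
# log frequency), on which normalising constants cancel.

#' Independent Dirichlet priors for the two groups
#'
#' @param a positive shape 3-vector (AA, AB, BB) for the case group.
#' @param b positive shape 3-vector for the control group.
#' @return An object of class `dirichlet_prior`. The all-ones default is
#'   the uniform distribution on each group's simplex.
#' @export
dirichlet_prior <- function(a = c(1, 1, 1), b = c(1, 1, 1)) {
  stopifnot(length(a) == 3, length(b) == 3, all(a > 0), all(b > 0))
  structure(list(a = stats::setNames(as.numeric(a), GENO),
                 b = stats::setNames(as.numeric(b), GENO)),
            class = "dirichlet_prior")
}

#' Conjugate posterior from genotype counts
#'
#' @param x a [genotype_table()].
#' @param prior a [dirichlet_prior()]; uniform by default.
#' @return An object of class `dirichlet_posterior` with shape vectors
#'   `alpha_case = counts + a` and `alpha_control = counts + b`.
#' @examples
#' gt <- genotype_table(c(55, 83, 50), c(24, 42, 39))
#' posterior_from_counts(gt)   # shapes (56, 84, 51) and (25, 43, 40)
#' @export
posterior_from_counts <- function(x, prior = dirichlet_prior()) {
  stopifnot(inherits(x, "genotype_table"), inherits(prior, "dirichlet_prior"))
  structure(list(alpha_case = x$case + prior$a,
                 alpha_control = x$control + prior$b,
                 prior = prior, table = x),
            class = "dirichlet_posterior")
}

#' Unnormalised log posterior density
#'
#' Evaluates `sum((alpha_case - 1) * log(gamma)) +
#' sum((alpha_control - 1) * log(pi))` with the `0 * log 0 := 0`
#' convention. This fixed unnormalised scale is the one on which all
#' tangential-set comparisons are made; adding any constant to it leaves
#' every e-value unchanged.
#'
#' @param post a `dirichlet_posterior`.
#' @param gamma,pi probability 3-vectors for case and control. `pi` may be
#'   omitted for single-group use (only the case factor is evaluated).
#' @return Scalar log density (possibly `-Inf`).
#' @export
log_posterior_density <- function(post, gamma, pi = NULL) {
  stopifnot(inherits(post, "dirichlet_posterior"))
  gamma <- check_prob3(gamma, "gamma")
  out <- kernel_loglik(gamma, as.numeric(post$alpha_case) - 1)
  if (!is.null(pi)) {
    pi <- check_prob3(pi, "pi")
    out <- out + kernel_loglik(pi, as.numeric(post$alpha_control) - 1)
  }
  out
}

# Exponent vectors (shape - 1) for the hypothesis' ambient space.
post_exponents <- function(post, kind) {
  switch(kind,
    hwe_case = list(e = as.numeric(post$alpha_case) - 1),
    hwe_control = list(e = as.numeric(post$alpha_control) - 1),
    list(ex = as.numeric(post$alpha_case) - 1,
         ey = as.numeric(post$alpha_control) - 1))
}

#' Supremum of the posterior density over a null set
#'
#' Finds the maximum of the unnormalised log posterior density over the
#' null set of the given hypothesis:
#' * genotypic homogeneity -- closed form: the common vector proportional
#'   to the pooled exponents `alpha_case + alpha_control - 2` (numerical
#'   fallback on the common simplex if any pooled exponent is negative);
#' * allelic homogeneity -- profile maximisation over the shared allele
#'   frequency with closed-form inner step (same engine as
#'   [fit_allelic_null()], exponents `alpha - 1`);
#' * Hardy-Weinberg (either group) -- along the curve
#'   `(p^2, 2p(1-p), (1-p)^2)` the maximiser is the closed form
#'   `p* = (2 e_AA + e_AB) / (2 (e_AA + e_AB + e_BB))` for exponents
#'   `e = alpha - 1`.
#'
#' @param post a `dirichlet_posterior`.
#' @param hypothesis hypothesis kind (see [hypothesis_spec()]) or a spec.
#' @return List with `arg_sup` (a list with `gamma` and `pi`, or a single
#'   3-vector plus `p` for HWE) and `sup_log_density` on the scale of
#'   [log_posterior_density()].
#' @export
sup_under_null <- function(post, hypothesis) {
  stopifnot(inherits(post, "dirichlet_posterior"))
  hyp <- if (is.list(hypothesis)) hypothesis else hypothesis_spec(hypothesis)
  ee <- post_exponents(post, hyp$kind)
  switch(hyp$kind,
    genotypic = {
      pooled <- ee$ex + ee$ey
      if (all(pooled >= 0) && sum(pooled) > 0) {
        p <- pooled / sum(pooled)
      } else {
        p <- sup_common_simplex(ee$ex, ee$ey)
      }
      p <- stats::setNames(p, GENO)
      list(arg_sup = list(gamma = p, pi = p),
           sup_log_density = kernel_loglik(p, ee$ex) +
             kernel_loglik(p, ee$ey))
    },
    allelic = {
      f <- fit_allelic_kernel(ee$ex, ee$ey)
      # The genotypic null set is contained in the allelic one, so its
      # supremum is a feasible lower bound; taking the max protects the
      # monotonicity guarantee against optimisation round-off.
      g <- sup_under_null(post, "genotypic")
      if (g$sup_log_density > f$log_lik) {
        list(arg_sup = g$arg_sup, sup_log_density = g$sup_log_density)
      } else {
        list(arg_sup = list(gamma = f$gamma, pi = f$pi),
             sup_log_density = f$log_lik)
      }
    },
    {
      e <- ee$e
      if (any(e < 0)) {
        stop("HWE supremum requires posterior shapes >= 1", call. = FALSE)
      }
      tot <- sum(e)
      p <- if (tot > 0) (2 * e[1L] + e[2L]) / (2 * tot) else 0.5
      g <- stats::setNames(c(p^2, 2 * p * (1 - p), (1 - p)^2), GENO)
      list(arg_sup = list(theta = g, p = p),
           sup_log_density = kernel_loglik(g, e))
    })
}

# Numerical maximisation of the pooled kernel on the common 2-simplex, used
# only when some pooled exponent is negative (sub-uniform priors with zero
# counts). Nelder-Mead on two free coordinates with a feasibility penalty.
sup_common_simplex <- function(ex, ey) {
  obj <- function(par) {
    p <- c(par, 1 - sum(par))
    if (any(p < 0) || any(p > 1)) return(1e10)
    -(kernel_loglik(p, ex) + kernel_loglik(p, ey))
  }
  best <- NULL
  for (start in list(c(1 / 3, 1 / 3), c(0.1, 0.8), c(0.8, 0.1),
                     c(0.45, 0.1))) {
    o <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  p <- c(best$par, 1 - sum(best$par))
  pmin(pmax(p, 0), 1)
}

# n_draws x 3 matrix of Dirichlet(shape) draws via normalised Gammas.
rdirichlet3 <- function(n_draws, shape) {
  g <- matrix(stats::rgamma(n_draws * 3L, shape = rep(shape, each = n_draws)),
              nrow = n_draws, ncol = 3L)
  g / rowSums(g)
}

# Log kernel for a matrix of draws (rows) under exponent vector e.
draw_log_kernel <- function(draws, e) {
  out <- numeric(nrow(draws))
  for (j in 1:3) {
    if (e[j] != 0) {
      lg <- log(draws[, j])
      lg[draws[, j] == 0] <- if (e[j] > 0) -Inf else Inf
      out <- out + e[j] * lg
    }
  }
  out
}

#' FBST e-value for a sharp hypothesis
#'
#' Computes the Full Bayesian Significance Test evidence value: draws from
#' the (product) Dirichlet posterior, evaluates the unnormalised log density
#' of every draw, and returns one minus the fraction of draws whose density
#' strictly exceeds the supremum of the density over the null set. Large
#' e-values support the hypothesis; small ones refute it. For the
#' Hardy-Weinberg hypotheses only the named group's own simplex (and
#' posterior factor) is involved.
#'
#' @param x a [genotype_table()].
#' @param hypothesis `"genotypic"`, `"allelic"`, `"hwe_case"` or
#'   `"hwe_control"` (or a [hypothesis_spec()]).
#' @param prior a [dirichlet_prior()]; uniform by default.
#' @param n_draws posterior Monte-Carlo draws (>= 1000; default 1e5 gives
#'   Monte-Carlo standard error at most 0.0016).
#' @param seed RNG seed; drawn at random (and recorded) when `NULL`.
#' @return An object of class `evalue_result`: `evalue`, `mc_se`,
#'   `sup_log_density`, `arg_sup`, `n_draws`, `seed`, `hypothesis`.
#' @examples
#' gt <- genotype_table(c(55, 83, 50), c(24, 42, 39))
#' evalue(gt, "genotypic", n_draws = 5000, seed = 1)
#' @export
evalue <- function(x, hypothesis, prior = dirichlet_prior(),
                   n_draws = 100000, seed = NULL) {
  stopifnot(inherits(x, "genotype_table"), n_draws >= 1000)
  hyp <- if (is.list(hypothesis)) hypothesis else hypothesis_spec(hypothesis)
  post <- posterior_from_counts(x, prior)
  sup <- sup_under_null(post, hyp)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  ld <- with_seed(seed, posterior_log_densities(post, hyp$kind, n_draws))
  ev <- 1 - mean(ld > sup$sup_log_density)
  structure(
    list(hypothesis = hyp, evalue = ev,
         mc_se = sqrt(ev * (1 - ev) / n_draws),
         sup_log_density = sup$sup_log_density, arg_sup = sup$arg_sup,
         n_draws = n_draws, seed = seed),
    class = "evalue_result")
}

# Posterior draws' log densities on the hypothesis' ambient scale.
posterior_log_densities <- function(post, kind, n_draws) {
  if (kind %in% c("hwe_case", "hwe_control")) {
    shape <- if (kind == "hwe_case") post$alpha_case else post$alpha_control
    d <- rdirichlet3(n_draws, as.numeric(shape))
    draw_log_kernel(d, as.numeric(shape) - 1)
  } else {
    G <- rdirichlet3(n_draws, as.numeric(post$alpha_case))
    P <- rdirichlet3(n_draws, as.numeric(post$alpha_control))
    draw_log_kernel(G, as.numeric(post$alpha_case) - 1) +
      draw_log_kernel(P, as.numeric(post$alpha_control) - 1)
  }
}

#' Genotypic and allelic e-values from one shared set of posterior draws
#'
#' Computes the e-values of the two nested homogeneity hypotheses using the
#' same posterior sample for both. Because the genotypic null set is
#' contained in the allelic one, its density supremum cannot exceed the
#' allelic supremum, and with shared draws the monotonicity
#' `ev(genotypic) <= ev(allelic)` then holds draw-by-draw -- not merely up
#' to Monte-Carlo error. This is the form used by the coherence auditor.
#'
#' @inheritParams evalue
#' @return List with `genotypic` and `allelic` `evalue_result` objects
#'   (identical `n_draws` and `seed`).
#' @export
evalue_pair <- function(x, prior = dirichlet_prior(), n_draws = 100000,
                        seed = NULL) {
  stopifnot(inherits(x, "genotype_table"), n_draws >= 1000)
  post <- posterior_from_counts(x, prior)
  sup_g <- sup_under_null(post, "genotypic")
  sup_a <- sup_under_null(post, "allelic")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  ld <- with_seed(seed, posterior_log_densities(post, "genotypic", n_draws))
  mk <- function(kind, sup) {
    ev <- 1 - mean(ld > sup$sup_log_density)
    structure(
      list(hypothesis = hypothesis_spec(kind), evalue = ev,
           mc_se = sqrt(ev * (1 - ev) / n_draws),
           sup_log_density = sup$sup_log_density, arg_sup = sup$arg_sup,
           n_draws = n_draws, seed = seed),
      class = "evalue_result")
  }
  list(genotypic = mk("genotypic", sup_g), allelic = mk("allelic", sup_a))
}

#' @export
print.evalue_result <- function(x, digits = 4, ...) {
  cat(sprintf("FBST e-value for the %s hypothesis\n", x$hypothesis$kind))
  cat(sprintf("  e-value = %s (MC se %s, %d draws, seed %s)\n",
              format(x$evalue, digits = digits),
              format(x$mc_se, digits = 2), x$n_draws, format(x$seed)))
  invisible(x)
}

#' E-value rejection cutoff matching a significance level
#'
#' Translates a frequentist significance level into an e-value threshold
#' through the asymptotic link between e-values and p-values: with ambient
#' dimension `d` and null dimension `null_dim`, reject the hypothesis when
#' the e-value is at most
#' `1 - F_d( F^{-1}_{d - null_dim}(1 - alpha) )`,
#' where `F_k` is the chi-square CDF with `k` degrees of freedom.
#'
#' @param alpha significance level in (0, 1).
#' @param d ambient parameter dimension.
#' @param null_dim dimension of the null set (`1 <= null_dim < d`).
#' @return List (`calibration_rule`): `alpha`, `d`, `null_dim`, `cutoff`.
#' @examples
#' evalue_cutoff(0.05, 4, 3)  # allelic homogeneity: ~0.4276
#' evalue_cutoff(0.05, 4, 2)  # genotypic homogeneity: ~0.1998
#' @export
evalue_cutoff <- function(alpha, d, null_dim) {
  stopifnot(alpha > 0, alpha < 1, null_dim >= 1, null_dim < d)
  q <- stats::qchisq(1 - alpha, df = d - null_dim)
  structure(list(alpha = alpha, d = d, null_dim = null_dim,
                 cutoff = stats::pchisq(q, df = d, lower.tail = FALSE)),
            class = "calibration_rule")
}

#' Bayes factor under uniform priors
#'
#' Bayes factor `P(data | H) / P(data | full model)` with uniform
#' distributions on the full parameter space and on the null set. For
#' genotypic homogeneity both marginal likelihoods are closed-form Dirichlet
#' integrals (the multinomial coefficients cancel in the ratio). For
#' allelic homogeneity the null-set marginal is computed by Monte-Carlo
#' integration under a Lebesgue-uniform measure in the coordinates
#' `(gamma_AB, Pi_AA, Pi_AB)` over the feasible region; note that "uniform
#' on the null set" does not single out one measure on a 3-dimensional
#' manifold, so the convention is part of the result's definition and is
#' recorded here.
#'
#' @param x a [genotype_table()].
#' @param hypothesis `"genotypic"` or `"allelic"`.
#' @param n_draws Monte-Carlo points for the allelic null integral.
#' @param seed RNG seed for the Monte-Carlo integral.
#' @return List with `bf` (the Bayes factor in favour of the hypothesis),
#'   `log_bf`, `hypothesis`, `convention`, and for the allelic case `mc_se_log`
#'   (delta-method standard error of `log_bf`).
#' @export
bayes_factor <- function(x, hypothesis = c("genotypic", "allelic"),
                         n_draws = 200000, seed = NULL) {
  stopifnot(inherits(x, "genotype_table"))
  hypothesis <- match.arg(hypothesis)
  cx <- as.numeric(x$case)
  cy <- as.numeric(x$control)
  n <- x$n
  m <- x$m
  # log E_uniform[kernel] over one simplex = log [ Gamma(3) prod Gamma(c+1)
  # / Gamma(N+3) ] ; coefficient-free kernels are used consistently in
  # numerator and denominator, so multinomial coefficients cancel.
  lmarg_simplex <- function(cnt) {
    lgamma(3) + sum(lgamma(cnt + 1)) - lgamma(sum(cnt) + 3)
  }
  lden <- lmarg_simplex(cx) + lmarg_simplex(cy)
  if (hypothesis == "genotypic") {
    lnum <- lmarg_simplex(cx + cy)
    return(list(bf = exp(lnum - lden), log_bf = lnum - lden,
                hypothesis = hypothesis,
                convention = "uniform on each simplex / common simplex"))
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  lw <- with_seed(seed, {
    g2 <- stats::runif(n_draws)
    pa <- stats::runif(n_draws)
    pb <- stats::runif(n_draws)
    ga <- pa + pb / 2 - g2 / 2
    gb <- 1 - ga - g2
    pbb <- 1 - pa - pb
    ok <- ga >= 0 & gb >= 0 & pbb >= 0 & ga <= 1 & gb <= 1 & pbb <= 1
    lk <- rep(-Inf, n_draws)
    lk[ok] <- cx[1] * log(ga[ok]) + cx[2] * log(g2[ok]) +
      cx[3] * log(gb[ok]) + cy[1] * log(pa[ok]) + cy[2] * log(pb[ok]) +
      cy[3] * log(pbb[ok])
    lk[ok][!is.finite(lk[ok])] <- -Inf  # zero frequency with positive count
    list(lk = lk[ok], n_ok = sum(ok))
  })
  mx <- max(lw$lk)
  w <- exp(lw$lk - mx)
  lnum <- mx + log(mean(w))
  se_log <- stats::sd(w) / (sqrt(lw$n_ok) * mean(w))
  list(bf = exp(lnum - lden), log_bf = lnum - lden, hypothesis = hypothesis,
       mc_se_log = se_log, n_draws = lw$n_ok, seed = seed,
       convention = paste("Lebesgue-uniform in (gamma_AB, Pi_AA, Pi_AB)",
                          "over the feasible null region"))
}
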