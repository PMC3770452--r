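# Maximisation of the product-multinomial likelihood (or any product of two
# Dirichlet kernels) under the allelic-homogeneity constraint
#   gamma_AA + gamma_AB/2 = Pi_AA + Pi_AB/2  ( = lambda, the shared A freq).
#
# The key structural fact: once lambda is fixed, the two groups decouple and
# each group's maximisation over its own heterozygote frequency t has a
# closed form. Writing a group's frequencies as
#   (lambda - t/2, t, 1 - lambda - t/2),  t in [0, 2 min(lambda, 1 - lambda)],
# the stationarity condition of
#   e1 log(lambda - t/2) + e2 log t + e3 log(1 - lambda - t/2)
# is the quadratic
#   (E/4) t^2 - [e2 + e1 (1 - lambda) + e3 lambda] t / 2
#     + e2 lambda (1 - lambda) = 0,   E = e1 + e2 + e3,
# whose smaller root is the unique interior maximiser (the objective is
# strictly concave in t). The outer problem is then a smooth 1-D profile
# maximisation over lambda, solved by a coarse grid bracket plus Brent
# refinement. Exponents e may be any non-negative reals, so the same engine
# serves the frequentist constrained MLE (e = counts) and the FBST null
# supremum (e = posterior shape - 1).

# Closed-form inner maximiser: heterozygote frequency t for one group.
inner_het <- function(lambda, e) {
  tmax <- 2 * min(lambda, 1 - lambda)
  if (tmax <= 0) return(0)
  if (e[2L] == 0) return(0)          # no heterozygote weight: t = 0 maximises
  total <- sum(e)
  if (total == 0) return(tmax / 2)   # flat objective: any feasible t
  a <- total / 4
  b <- -(e[2L] + e[1L] * (1 - lambda) + e[3L] * lambda) / 2
  cc <- e[2L] * lambda * (1 - lambda)
  disc <- max(b * b - 4 * a * cc, 0)
  t <- (-b - sqrt(disc)) / (2 * a)
  min(max(t, 0), tmax)
}

# Kernel log "likelihood" sum(e * log g) with the 0 * log 0 := 0 convention.
kernel_loglik <- function(g, e) {
  pos <- e > 0
  if (!any(pos)) return(0)
  if (any(g[pos] <= 0)) return(-Inf)
  sum(e[pos] * log(g[pos]))
}

profile_loglik <- function(lambda, ex, ey) {
  tx <- inner_het(lambda, ex)
  ty <- inner_het(lambda, ey)
  kernel_loglik(c(lambda - tx / 2, tx, 1 - lambda - tx / 2), ex) +
    kernel_loglik(c(lambda - ty / 2, ty, 1 - lambda - ty / 2), ey)
}

# Maximise the constrained kernel over the allelic null set.
# ex, ey: non-negative real exponent 3-vectors for case / control.
# Returns gamma, pi, the shared allele frequency lambda, the achieved log
# kernel, and a boundary flag.
fit_allelic_kernel <- function(ex, ey, grid_n = 21L, tol = 1e-10) {
  if (any(ex < 0) || any(ey < 0)) {
    stop("exponents must be non-negative (priors with shape < 1 and zero ",
         "counts make the constrained supremum unbounded)", call. = FALSE)
  }
  # Candidate bracket from a coarse grid (the profile is smooth; the grid
  # guards against the rare flat/boundary geometries).
  grid <- seq(0, 1, length.out = grid_n)
  vals <- vapply(grid, profile_loglik, numeric(1), ex = ex, ey = ey)
  k <- which.max(vals)
  lo <- grid[max(k - 1L, 1L)]
  hi <- grid[min(k + 1L, grid_n)]
  if (hi - lo < 1e-12) {
    lam <- grid[k]
    best <- vals[k]
  } else {
    opt <- stats::optimize(profile_loglik, c(lo, hi), ex = ex, ey = ey,
                           maximum = TRUE, tol = tol)
    # Boundary candidates (all-A or all-B): optimize() cannot land exactly
    # on 0 or 1, where the kernel can still dominate for monomorphic data.
    cand_l <- c(opt$maximum, grid[k])
    cand_v <- c(opt$objective, vals[k])
    lam <- cand_l[which.max(cand_v)]
    best <- max(cand_v)
  }
  tx <- inner_het(lam, ex)
  ty <- inner_het(lam, ey)
  gamma <- c(lam - tx / 2, tx, 1 - lam - tx / 2)
  pi <- c(lam - ty / 2, ty, 1 - lam - ty / 2)
  gamma <- pmin(pmax(gamma, 0), 1)
  pi <- pmin(pmax(pi, 0), 1)
  list(gamma = stats::setNames(gamma, GENO),
       pi = stats::setNames(pi, GENO),
       lambda = lam,
       log_lik = best,
       boundary = any(c(gamma, pi) < 1e-9))
}

#' Constrained maximum-likelihood fit under allelic homogeneity
#'
#' Maximises the product-multinomial likelihood of the 2x3 genotype table
#' over the null set where the two groups share the same allele-A frequency
#' (`gamma_AA + gamma_AB/2 = Pi_AA + Pi_AB/2`), without assuming
#' Hardy-Weinberg equilibrium in either group. The full genotype-frequency
#' estimates for both groups are returned together with the expected counts
#' they imply; these are the ingredients of the corrected allelic chi-square
#' statistic (see [allelic_test_corrected()]).
#'
#' The maximisation profiles out the shared allele frequency: for fixed
#' allele frequency the optimal heterozygote frequency of each group solves
#' a quadratic in closed form, and the remaining one-dimensional profile is
#' maximised numerically (grid bracket + Brent, objective tolerance 1e-10).
#'
#' @param x a [genotype_table()].
#' @param prior_counts optional non-negative pseudo-count added to every
#'   cell before fitting (default 0, the pure MLE).
#' @return An object of class `fitted_null`: hypothesis spec, `gamma` and
#'   `pi` estimates, shared allele frequency `lambda`, `expected_case`,
#'   `expected_control`, `log_lik` (product-multinomial log kernel at the
#'   maximum), and flags `converged`, `boundary`.
#' @examples
#' gt <- genotype_table(c(55, 83, 50), c(24, 42, 39))
#' fit_allelic_null(gt)
#' @export
fit_allelic_null <- function(x, prior_counts = 0) {
  stopifnot(inherits(x, "genotype_table"), prior_counts >= 0)
  ex <- as.numeric(x$case) + prior_counts
  ey <- as.numeric(x$control) + prior_counts
  f <- fit_allelic_kernel(ex, ey)
  structure(
    list(hypothesis = hypothesis_spec("allelic"),
         gamma = f$gamma, pi = f$pi, lambda = f$lambda,
         expected_case = x$n * f$gamma,
         expected_control = x$m * f$pi,
         log_lik = kernel_loglik(f$gamma, as.numeric(x$case)) +
                   kernel_loglik(f$pi, as.numeric(x$control)),
         converged = TRUE, boundary = f$boundary),
    class = "fitted_null")
}

#' Pooled maximum-likelihood fit under genotypic homogeneity
#'
#' Under genotypic homogeneity both groups share one genotype frequency
#' vector, whose MLE is the pooled relative frequency
#' `(x_i + y_i) / (n + m)`. Expected counts are the pooled estimate scaled
#' by each group's size.
#'
#' @param x a [genotype_table()].
#' @return A `fitted_null` object (with `gamma` = `pi` = pooled estimate).
#' @export
fit_pooled <- function(x) {
  stopifnot(inherits(x, "genotype_table"))
  theta <- (as.numeric(x$case) + as.numeric(x$control)) / (x$n + x$m)
  theta <- stats::setNames(theta, GENO)
  structure(
    list(hypothesis = hypothesis_spec("genotypic"),
         gamma = theta, pi = theta, lambda = theta[["AA"]] + theta[["AB"]] / 2,
         expected_case = x$n * theta,
         expected_control = x$m * theta,
         log_lik = kernel_loglik(theta, as.numeric(x$case)) +
                   kernel_loglik(theta, as.numeric(x$control)),
         converged = TRUE, boundary = any(theta == 0)),
    class = "fitted_null")
}

#' @export
print.fitted_null <- function(x, ...) {
  cat("Constrained fit under the", x$hypothesis$kind, "null\n")
  est <- rbind(`gamma (case)` = x$gamma, `Pi (control)` = x$pi)
  print(round(est, 5))
  cat("shared allele-A frequency:", format(x$lambda, digits = 6), "\n")
  cat("log-likelihood kernel:", format(x$log_lik, digits = 8), "\n")
  if (isTRUE(x$boundary)) cat("note: estimate on the simplex boundary\n")
  invisible(x)
}
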