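# Shared fixtures and independent oracles used across the suite.

# The published GABA-A case-control table (case 55/83/50, control 24/42/39).
gaba_table <- function() genotype_table(c(55, 83, 50), c(24, 42, 39))

# Batch of random tables drawn from random product-multinomial models.
random_tables <- function(k, seed = 1, n = 60, m = 40) {
  set.seed(seed)
  out <- vector("list", k)
  for (i in seq_len(k)) {
    repeat {
      g <- rgamma(3, 1); g <- g / sum(g)
      p <- rgamma(3, 1); p <- p / sum(p)
      tab <- try(genotype_table(as.vector(rmultinom(1, n, g)),
                                as.vector(rmultinom(1, m, p))),
                 silent = TRUE)
      if (!inherits(tab, "try-error")) break
    }
    out[[i]] <- tab
  }
  out
}

# All compositions of n into 3 non-negative parts (rows).
compositions3 <- function(n) {
  out <- NULL
  for (a in 0:n) for (b in 0:(n - a)) out <- rbind(out, c(a, b, n - a - b))
  out
}

# Exact parametric-bootstrap p-value by full enumeration of the
# product-multinomial null: sum of null probabilities of all (X, Y)
# outcomes whose statistic is >= the observed one. Independent of the
# Monte-Carlo engine.
exact_boot_p <- function(tab, stat_fn, fit) {
  obs <- stat_fn(tab)
  cx <- compositions3(tab$n)
  cy <- compositions3(tab$m)
  px <- apply(cx, 1, function(x) dmultinom(x, prob = as.numeric(fit$gamma)))
  py <- apply(cy, 1, function(y) dmultinom(y, prob = as.numeric(fit$pi)))
  p <- 0
  for (i in seq_len(nrow(cx))) {
    if (px[i] == 0) next
    for (j in seq_len(nrow(cy))) {
      if (py[j] == 0) next
      s <- stat_fn(genotype_table(cx[i, ], cy[j, ]))
      if (s >= obs) p <- p + px[i] * py[j]
    }
  }
  p
}

# Grid search of the product-multinomial log-likelihood over the allelic
# null manifold in coordinates (gamma_AB, Pi_AA, Pi_AB); returns the best
# log-likelihood found. Chunked over gamma_AB to bound memory.
grid_max_null_loglik <- function(tab, step = 0.005) {
  x <- as.numeric(tab$case); y <- as.numeric(tab$control)
  ll3 <- function(gA, g2, gB, e) {
    out <- 0
    for (p in list(list(gA, e[1]), list(g2, e[2]), list(gB, e[3]))) {
      if (p[[2]] > 0) {
        lg <- suppressWarnings(log(p[[1]]))
        lg[p[[1]] <= 0] <- -Inf
        out <- out + p[[2]] * lg
      }
    }
    out
  }
  grid <- seq(0, 1, by = step)
  best <- -Inf
  mesh <- expand.grid(pA = grid, pB = grid)
  for (g2 in grid) {
    gA <- mesh$pA + mesh$pB / 2 - g2 / 2
    gB <- 1 - gA - g2
    pBB <- 1 - mesh$pA - mesh$pB
    ok <- gA >= 0 & gB >= 0 & pBB >= 0
    if (!any(ok)) next
    v <- ll3(gA[ok], g2, gB[ok], x) + ll3(mesh$pA[ok], mesh$pB[ok], pBB[ok], y)
    best <- max(best, max(v))
  }
  best
}
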