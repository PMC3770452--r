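---
title: "Methods: nested homogeneity tests and the FBST"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nested homogeneity tests and the FBST}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical model, the algorithms, the tunable
parameters, and the design decisions behind `nestedhom`. It is a methods
reference, not a tutorial; see the README for a worked example.

# Model and assumptions

Data are a 2×3 genotype table at a biallelic locus: case counts
$x = (x_{AA}, x_{AB}, x_{BB})$ with $n = \sum x$ and control counts
$y = (y_{AA}, y_{AB}, y_{BB})$ with $m = \sum y$. The sampling model is
product-multinomial,

$$x \sim \mathrm{Mult}(n, \gamma), \qquad y \sim \mathrm{Mult}(m, \Pi),$$

with $\gamma, \Pi$ independent points of the 2-simplex, so the full
parameter space has dimension $d = 4$. Sample sizes $n, m$ are fixed by
design (retrospective sampling); nothing in the package assumes
Hardy-Weinberg equilibrium (HWE) unless a function says so explicitly.

Hypotheses, all sharp (lower-dimensional) subsets:

- **Genotypic homogeneity** $H_0^G : \gamma = \Pi$ (dimension 2).
- **Allelic homogeneity**
  $H_0^A : \gamma_{AA} + \gamma_{AB}/2 = \Pi_{AA} + \Pi_{AB}/2$
  (dimension 3). $H_0^G \subset H_0^A$, so the hypotheses are nested.
- **HWE within one group**, e.g.
  $\gamma = (\lambda^2, 2\lambda(1-\lambda), (1-\lambda)^2)$
  (dimension 1 inside that group's simplex, $d = 2$).

Two pathologies motivate the package. First, the traditional allelic test
(`allelic_test_usual`) compares allele counts $(2x_{AA}+x_{AB},\ldots)$ in
a 2×2 chi-square as if the $2n + 2m$ alleles were independent draws; that
holds only under HWE in both groups, and otherwise the test's true size is
wrong in either direction. Second, because the hypotheses are nested,
p-values that reject $H_0^A$ while accepting $H_0^G$ at the same level are
logically incoherent; this happens with real data and is detected by
`coherence_audit` and flagged by `run_analysis`.

# Frequentist tests

`genotypic_test` is the usual 2-df Pearson chi-square on the 2×3 table.
`allelic_test_usual` is the 1-df chi-square on allele counts, returned with
a standing validity warning. `armitage_trend_test` is the Cochran-Armitage
trend test with scores (2, 1, 0), the asymptotically correct 1-df allelic
test. `hwe_test` is the 1-df goodness-of-fit test within one group.

The centrepiece, `allelic_test_corrected`, stays at genotype level. The
statistic is

$$Q^{A*} = \min_{(\gamma,\Pi) \in H_0^A}
  \sum_{\text{6 cells}} \frac{(\text{obs} - \text{exp})^2}{\text{exp}},$$

a Pearson distance from the data to the best-fitting point of the null
manifold, with $4 - 3 = 1$ degree of freedom asymptotically.

**Constrained MLE.** The spec for a generic optimiser would be a 3-D
search; we instead profile. Parameterise the null manifold by the common
allele frequency $\lambda$ and the two heterozygote frequencies: a group
with allele frequency $\lambda$ and heterozygote frequency $t$ has
genotype frequencies $(\lambda - t/2,\ t,\ 1 - \lambda - t/2)$. For fixed
$\lambda$ the log-likelihood separates across groups, and the inner optimum
in $t$ for exponents $(e_1, e_2, e_3)$ (with $E = e_1+e_2+e_3$) solves the
quadratic

$$\tfrac{E}{4} t^2 - \tfrac{1}{2}\bigl[e_2 + e_1(1-\lambda) +
  e_3 \lambda\bigr] t + e_2 \lambda (1-\lambda) = 0,$$

whose smaller root is the maximiser (the objective is concave on the
feasible interval). The outer problem is a 1-D maximisation over
$\lambda \in (0, 1)$: a 21-point coarse grid to bracket, then Brent
(`optimize`, tolerance `1e-10`). This runs in microseconds, which is what
makes 100,000 bootstrap re-fits affordable (~30 s), and it accepts any
non-negative real exponents — counts for the MLE, Dirichlet shape
parameters minus one for the FBST supremum — so one routine
(`fit_allelic_kernel`) serves both.

**Exact p-value.** `method = "mc"` draws `n_reps` parametric-bootstrap
tables at the constrained MLE (for the corrected test) or the pooled MLE
(for the others), recomputes the statistic on each — including the
constrained re-fit — and reports the proportion of replicates with
statistic $\ge$ the observed one (ties count toward the p-value, the
conservative convention). A normal-approximation 95 % CI accompanies it.
Replicates whose fit fails are dropped; more than 1 % failures aborts
rather than silently biasing the estimate.

**Numerical conventions.** $0 \log 0 := 0$ throughout. Pearson cell terms
with expected 0 contribute 0 when observed is 0 and $\infty$ otherwise.
The corrected statistic is snapped to 0 when below `1e-9`: Brent leaves a
$\sim 10^{-12}$ residual on tables that satisfy the null exactly, and
without the snap such a table's bootstrap p-value would not be exactly 1
because replicates can tie at a true 0 below the residual.

# FBST e-values

With independent Dirichlet priors (`dirichlet_prior`, default uniform
$\alpha = (1,1,1)$ per group) the posterior is product-Dirichlet with
shapes counts + prior. The evidence value of a sharp hypothesis
$\Theta_0$ is

$$\mathrm{ev}(\Theta_0) = 1 - \Pr\bigl(f(\theta \mid x) >
  \sup_{\Theta_0} f(\theta \mid x) \,\big|\, x\bigr),$$

estimated by Monte Carlo: `n_draws` product-Dirichlet draws (normalised
Gammas), each scored by the unnormalised log kernel
$\sum (\alpha_i - 1) \log \theta_i$; the normalising constant cancels on
both sides of the strict inequality.

Suprema over the null sets:

- $H_0^G$: closed form — the common simplex point has coordinates
  proportional to $\alpha^{case}_i + \alpha^{ctrl}_i - 2$ when all are
  positive, with a Nelder-Mead fallback otherwise.
- $H_0^A$: the profile optimiser above with exponents $\alpha - 1$, then
  $\sup_A := \max(\text{numerical}, \sup_G)$. Since
  $H_0^G \subset H_0^A$ the true $\sup_A \ge \sup_G$; taking the max
  guarantees the inequality survives finite numerical tolerance.
- HWE: closed form $\lambda^* = (2e_{AA} + e_{AB}) / (2\sum e)$.

**Coherence by construction.** `evalue_pair` evaluates both homogeneity
hypotheses on the *same* posterior draws. Combined with
$\sup_A \ge \sup_G$, the tangential set of $H_0^G$ contains that of
$H_0^A$ draw by draw, so the reported pair always satisfies
$\mathrm{ev}(H_0^G) \le \mathrm{ev}(H_0^A)$ exactly, not just in
expectation. The property test checks this on hundreds of random tables.

**Cutoff calibration.** `evalue_cutoff(alpha, d, null_dim)` returns
$1 - F_d\bigl(F^{-1}_{d-h}(1 - \alpha)\bigr)$ with $F_k$ the
$\chi^2_k$ CDF: the asymptotic e-value threshold matching a level-$\alpha$
test of an $h$-dimensional null in a $d$-dimensional model (e.g. 0.42789
for $d=4, h=3$; 0.19979 for $d=4, h=2$). Note the function is monotone
*increasing* in $\alpha$ (limits 0 at $\alpha \to 0$ and 1 at
$\alpha \to 1$), which is the direction the tests assert.

**Bayes factors.** `bayes_factor` is provided for completeness. For
$H_0^G$ the Dirichlet integrals are closed-form. For $H_0^A$ the prior
measure on a 3-dimensional sharp hypothesis is a genuine modelling choice;
we take Lebesgue-uniform in the chart
$(\gamma_{AB}, \Pi_{AA}, \Pi_{AB})$ and integrate by Monte Carlo
(log-sum-exp). Other charts give other numbers; no headline quantity
depends on this choice.

# Simulation machinery

`sample_table` draws product-multinomial tables. `build_scenario` builds
alternatives at controlled allelic distance: given
$(\gamma, \Pi_{AA}, \varepsilon)$ it sets
$\Pi_{AB} = 2(\gamma_{AA} + \gamma_{AB}/2 - \Pi_{AA} - \varepsilon)$, so
$\varepsilon$ is exactly the allele-frequency difference; infeasible
combinations error with the violated bound named. `table6_regimes` yields
generators for three strata — both groups in HWE, one out, both out — used
to study the usual test's size distortion. `power_curve` runs seeded
size/power studies over an $\varepsilon$ grid for any subset of the tests
(FBST rejections use `evalue_cutoff`); each grid point gets an independent
seed substream so results are reproducible point-wise.
`coherence_audit` runs all tests on a list of observed tables and reports,
per table, whether the usual or corrected p-values are incoherent with the
genotypic one at level $\alpha$ and whether the e-value pair violates
monotonicity (it never does).

What the generator emulates: retrospective case-control sampling with
fixed $n, m$ at a single biallelic locus, including HWE violations of
arbitrary direction. What it does not: covariates, population
stratification, genotyping error, linkage between loci, or
prospective/cohort sampling.

# Defaults and problem sizes

| Parameter | Default | Rationale |
|---|---|---|
| `n_reps` (bootstrap) | 10,000 (analysis), 100,000 (headline script) | MC s.e. of a p≈0.07 is ≈0.0008 at 1e5 |
| `n_draws` (FBST) | 10,000 (analysis), 100,000 (headline script) | e-value s.e. ≈0.0016 at 1e5 |
| profile grid / Brent tol | 21 points / `1e-10` | unimodal profile; grid only brackets |
| statistic snap | `1e-9` | above Brent residual, far below any real signal |
| `alpha` | 0.05 | conventional; cutoffs derived, not hard-coded |
| prior | uniform Dirichlet(1,1,1)² | reference analysis; any positive shapes allowed |
| MC failure budget | 1 % | a failing fit is a bug signal, not noise |

Typical problem sizes exercised in the tests: tables with $n, m$ from a
handful to a few hundred; 100,000-replicate bootstraps (~30 s); 100,000
posterior draws (<1 s); size studies of 2,000 datasets; full enumeration
oracles on tables with $n = m = 3$.

# Known limitations

- Biallelic loci only; no multi-allelic or multi-locus extension.
- The bootstrap p-value is exact only up to Monte-Carlo error and the
  plug-in at the constrained MLE (a parametric bootstrap, not a full
  enumeration over the null manifold); the CI quantifies the former.
- The allelic Bayes factor depends on an arbitrary chart choice, as
  discussed above.
- Asymptotic p-values (`method = "asymptotic"`) inherit the usual
  chi-square small-count caveats; prefer `method = "mc"` for small tables.
- `evalue_cutoff` is an asymptotic calibration; at small $n, m$ the
  FBST rejection rate at the cutoff need not equal $\alpha$ exactly.
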