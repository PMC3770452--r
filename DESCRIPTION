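Package: nestedhom
Title: Coherent Tests of Genotypic and Allelic Homogeneity in
    Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tests of genotypic and allelic homogeneity for a biallelic
    locus in case-control association studies, treating the two
    hypotheses as the nested pair they are. Provides the classical
    chi-square test of genotypic homogeneity, the traditional
    doubled-sample allelic test (valid only under Hardy-Weinberg
    equilibrium, and kept as the biased comparator), a corrected exact
    allelic test based on the constrained maximum-likelihood fit of the
    product-multinomial model with Monte-Carlo (parametric bootstrap)
    p-values, per-group Hardy-Weinberg goodness-of-fit tests, the
    Cochran-Armitage trend test, and the Full Bayesian Significance Test
    (FBST) whose e-values are provably monotone over nested hypotheses
    and therefore never reject allelic homogeneity while accepting
    genotypic homogeneity. Includes seeded simulation tools for type-I
    error and power studies and a coherence auditor that flags p-value
    incoherences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
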