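Package: epimax
Title: Penetrance Tables with Maximum Prevalence or Heritability for
    Bivariate Epistasis Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds numeric penetrance tables from epistasis models defined
    by bivariate penetrance expressions (one expression per multilocus
    genotype, all sharing a baseline-effect and a genotypic-effect
    variable). Given per-locus minor allele frequencies and a fixed
    heritability (or prevalence), solves for the variable values that
    maximize the prevalence (or heritability) subject to every penetrance
    lying in [0, 1], assuming Hardy-Weinberg and linkage equilibrium.
    Includes admissibility checks (monotonicity and sortability of the
    penetrance expressions over the positive quadrant), generators for
    additive, multiplicative and threshold model families at arbitrary
    interaction order, and writers for the GAMETES model-file format
    consumed by downstream case-control data simulators.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
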