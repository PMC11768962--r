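Package: synvar
Title: Exact Inbreeding and Founder-Sample Stability of Synthetic Varieties
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing the founder samples of a synthetic variety
    bred from selfed inbred lines at a single biallelic locus. Computes the
    inbreeding coefficient of the synthetic as an exact rational function of
    the per-line sample size m, the parental inbreeding coefficient F and the
    number of unrelated lines l; the exact probabilities that a random sample
    of m plants retains every genotype of the selfed-line genotypic array
    (by enumeration of integer partitions and their distinct permutations,
    cross-checked by inclusion-exclusion); the probabilities of allele loss
    and of equal allele frequencies in the sample; and a seeded gene-dropping
    Monte Carlo oracle that validates every analytic quantity. All analytic
    results use exact arbitrary-precision rational arithmetic; floating point
    appears only at presentation boundaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'bignat.R'
    'rational.R'
    'genetic-model.R'
    'inbreeding.R'
    'retention.R'
    'allele-stats.R'
    'simulation.R'
    'render.R'
    'cli.R'
    'synvar-package.R'
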