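Package: nichenull
Title: Niche Overlap, Null Models and Species Co-Occurrence for
    Community Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying spatial niche overlap in species-by-site
    abundance matrices and testing it against Monte Carlo null models.
    Implements Pianka's symmetric overlap index with species means and
    assemblage means, the RA1-RA4 randomisation algorithms for resource
    utilisation matrices with tail probabilities from simulated null
    assemblages, the Stone-Roberts C-score as a descriptive segregation
    statistic, mixed-design repeated-measures comparisons (Type III sums of
    squares, Bonferroni post hocs, paired t-tests) of overlap values across
    years, and a Dirichlet-multinomial synthetic community generator with
    tunable niche breadth and interspecific segregation so the whole
    pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
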