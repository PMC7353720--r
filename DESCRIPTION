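Package: admixepi
Title: Detecting Fitness Epistasis from Local-Ancestry Correlations in Admixed Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scans for fitness epistasis between loci on the same chromosome in
    a recently admixed population. Local-ancestry correlations between bins are
    decomposed into the expected admixture linkage-disequilibrium decay, fitted
    per locus as an exponential in genetic distance, and a residual excess
    correlation that is tested against a null scale estimated from
    cross-chromosome bin pairs. Cohort-level scans are combined by
    square-root-of-n weighted Z meta-analysis with Cochran's Q heterogeneity
    and genomic-control diagnostics, and candidate region pairs are
    corroborated by an ancestry-crossover deficit test and a positional
    enrichment test. A forward-time two-way admixture simulator under the
    hybrid-isolation model, with optional two-locus epistatic selection,
    provides ground-truth data for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
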