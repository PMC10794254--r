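Package: xwasmeta
Title: Sex-Stratified X-Chromosome-Wide Association Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for sex-stratified X-chromosome-wide
    association meta-analysis from per-study GWAS summary statistics:
    per-study quality control and X-dosage coding harmonization (male 0/2,
    female 0/1/2), genomic-control correction, fixed-effect inverse-variance
    meta-analysis with heterogeneity and frequency/info filters, iterative
    locus definition, sex-by-genotype interaction testing with an
    X-inactivation sensitivity analysis, stepwise conditional selection of
    independent signals, 99 percent credible sets from approximate Bayes
    factors with empirically estimated priors, Bayesian colocalization over
    five hypotheses, cross-trait classification, androgen-response-element
    enrichment testing and an ordered-criteria gene prioritization engine.
    Ships a summary-statistic simulator for multi-study, multi-ancestry,
    sex-stratified X-chromosome panels with configurable dosage codings,
    LD blocks, sex-specific effects and X-inactivation escape.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite,
    igraph,
    withr
Config/testthat/edition: 3
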