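Package: mnarch
Title: Genetic Architecture of Membranous Nephropathy: Simulation,
    Association Testing, and Combined Risk Scores
Version: 0.1.0
Authors@R:
    person("mnarch", "developers", email = "mnarch@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of the genetic-architecture analysis
    of primary membranous nephropathy: seeded case-control cohort simulation
    under a logistic liability model with epistasis, additive dosage
    association with stepwise conditioning, fixed-effects meta-analysis with
    heterogeneity statistics, multi-allelic HLA omnibus and conditional
    amino-acid haplotype tests, pairwise epistasis screening with Bonferroni
    control, Wakefield approximate-Bayes-factor credible sets, the published
    ethnicity-specific genetic risk score (GRS) and serology-combined risk
    score (CRS), and diagnostic evaluation (AUROC with DeLong confidence
    intervals, specificity-targeted cutoff tables, IDI/NRI, decile odds
    ratios, liability-scale heritability).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    VariantAnnotation
Config/testthat/edition: 3
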