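Package: homburden
Title: Runs of Homozygosity and Genomic Inbreeding in Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Paul", "Brennan", email = "pbrennan.genepi@gmail.com",
           role = c("aut", "cre"))
Description: Detection of runs of homozygosity (ROH) from SNP array
    genotypes with a windowed scan, pooling of overlapping ROHs into
    recurrent consensus regions with case-control carrier tests, per
    individual ROH burden summaries and quantile-binned odds ratios,
    SNP-wise genomic inbreeding coefficients (variance of additive
    values, excess homozygosity, correlation of uniting gametes) and the
    segment-based F_ROH, and covariate-adjusted logistic association of
    inbreeding with disease status including a permutation test based on
    regressor residuals.  Includes PLINK 1 text and binary readers and
    writers and a synthetic case-control cohort generator that plants
    known inbreeding levels and autozygous tracts for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
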