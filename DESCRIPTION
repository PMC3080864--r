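Package: ecoscan
Title: Environmental-Correlation Genome Scans with a Population-Structure Null
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Genome scans for local adaptation from population allele
    frequencies and environmental variables. Computes per-SNP Bayes factors
    for a linear environmental effect against a multivariate-normal null that
    models correlated genetic drift through an estimated across-population
    covariance matrix, converts them to ascertainment- and frequency-binned
    empirical rank statistics, and assesses tail enrichment of genic,
    nonsynonymous and gene-set SNP classes with 500-kb block-bootstrap
    significance. Includes population-subset scans, tail-overlap and
    rank-correlation comparisons, GWAS-catalog intersection, and a synthetic
    allele-count generator with planted environmental effects for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
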