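Package: snplogit
Title: Logistic Disease-Risk Models from Published SNP Odds Ratios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds calibrated logistic disease-risk-prediction models
    directly from literature-reported single-nucleotide polymorphism (SNP)
    odds ratios. Per-SNP coefficients are the natural logarithm of the
    reported heterozygous odds ratio; homozygous genotypes are encoded as
    dummy variables so their log-odds contribution equals the reported
    homozygous odds ratio; and the model intercept is calibrated against a
    stratum-specific population-average lifetime risk using Hardy-Weinberg
    genotype frequencies. Includes genotype input from VCF or tabular calls,
    absolute and relative lifetime-risk prediction with approximate
    delta-method intervals, cohort summaries, a synthetic-cohort and
    case/control simulator for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
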