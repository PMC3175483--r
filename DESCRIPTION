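Package: immunosig
Title: Statistical Modelling of Immunosignature Peptide Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analyzing immunosignature peptide-microarray
    experiments, in which serum antibodies bind thousands of
    random-sequence peptides and the resulting fluorescence pattern is
    mined for disease structure. Provides an intensity container built on
    SummarizedExperiment with GenePix-results (GPR) and delimited-table
    readers, per-slide median normalization on the log10 scale,
    Welch-Satterthwaite peptide screening with Bonferroni control,
    principal axis factoring with Varimax, Promax and Geomin rotation and
    loading-threshold sample classification, maximum-likelihood
    confirmatory factor analysis with chi-square, RMSEA and SRMR fit
    indices, latent-factor structural models of disease status with odds
    ratios, exploratory factor mixture models with BIC class enumeration,
    a ground-truth synthetic immunosignature generator, and an
    orchestrated latent-antibody discovery pipeline with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
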