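Package: CorePanel
Title: Core Marker Panels, Diversity Analysis and Genomic Prediction for
    Cereal Breeding
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Construction and evaluation of compact, evenly spaced core SNP
    marker panels for barley and wheat breeding programs. Candidate amplicon
    markers are filtered on missing rate and mapping-quality class and tiled
    across chromosomes preferring high minor allele frequency; the resulting
    panel is summarised by per-chromosome marker intervals and genome coverage.
    Multi-sample genotype matrices (VCF or dosage tables) are quality
    controlled and characterised by minor-allele-frequency profiles with LOESS
    smoothing, covariance-matrix principal component analysis, and linkage
    disequilibrium decay across fixed physical-distance classes. Genomic
    prediction uses a ridge-regression BLUP mixed model with spectral REML
    variance-component estimation, evaluated by repeated one-fifth hold-out
    cross-validation and cross-year prediction of station-and-year scaled
    phenotypes. A breeding-population simulator (Balding-Nichols subpopulation
    divergence, Haldane recombination, repeated selfing, polygenic traits with
    station-by-year location and scale shifts) provides ground truth for the
    test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: SNP, GenomicVariation, Genetics, QualityControl,
    DimensionReduction, Regression
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'CorePanel-package.R'
    'diversity.R'
    'genotypeQC.R'
    'io.R'
    'markerSelect.R'
    'prediction.R'
    'simulate.R'
    'utils.R'
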