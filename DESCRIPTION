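Package: swgsHRD
Title: Homologous Recombination Deficiency Calling from Shallow
    Whole-Genome Copy-Number Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decision engine for detecting homologous recombination
    deficiency (HRD) in tumors from shallow whole-genome sequencing
    (~1X) copy-number ratio profiles. Provides noise-aware circular
    binary segmentation with FFPE panel-of-normals artifact merging,
    counting of large genomic alterations (LGA), an LGA-score with
    penalties for nonHRD-associated attributes and a bonus for simple
    genomes, quality-dependent stepwise HRD/nonHRD/non-determined
    diagnostics with rerun confidence intervals, three-category
    diagnostic concordance statistics (agreement fractions and Cohen's
    kappa), and a ground-truth simulator for bin-level tumor profiles
    and normal FFPE panels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'genome.R'
    'io.R'
    'segment.R'
    'features.R'
    'classify.R'
    'concordance.R'
    'preprocess.R'
    'quality.R'
    'simulate.R'
    'report.R'
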