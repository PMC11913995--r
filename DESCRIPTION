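Package: spotEval
Title: Pre-Analytic Evaluation of Dried Blood and Plasma Spot Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quality assessment of LC-MS metabolomics and lipidomics feature
    tables from dried blood spot (DBS) and dried plasma spot (DPS)
    microsampling experiments. Implements a percentile-bin extraction score
    for ranking extraction solvents, coefficient-of-variation (CV%)
    reproducibility profiling with the standard <10/10-30/>30 buckets,
    short-term storage stability assessment against a +/-20% variation-to-
    baseline band, volcano comparison of single versus consecutive (two-step)
    extraction, a PCA overview, and BCA protein-assay calibration inversion.
    Ships a synthetic feature-table generator that emulates the device x
    solvent x replicate study design with lognormal replicate noise,
    detection limits and per-class storage decay, exposing its ground truth
    for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Metabolomics, Lipidomics, QualityControl, Preprocessing
RoxygenNote: 7.3.3
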