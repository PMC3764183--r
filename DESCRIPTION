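Package: telostress
Title: Stress-Driven Telomere Length Homeostasis Analysis in Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for linking environmental stresses to telomere-length
    change in budding yeast. Implements gel-lane densitometry calibration
    and telomere fragment length estimation from two size-marker bands,
    two-class Significance Analysis of Microarrays (SAM) with
    permutation-based false discovery rate control and detection-call
    filtering, a network-proximity rank-sum test for stress-specific
    differentially expressed telomere length maintenance (TLM) genes,
    a robust-regression screen for over- and under-responsive deletion
    mutants, and ChIP fold-enrichment quantification. A synthetic-data
    module generates every input with known ground truth for calibration
    and parameter-recovery testing, and a pipeline driver runs all stages
    end to end from a YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    yaml,
    S4Vectors,
    SummarizedExperiment,
    withr
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
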