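Package: hsp90flux
Title: Proteome Turnover and Expression Dynamics Under Hsp90 Inhibition
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for quantitative proteomics studies of
    chaperone inhibition. Implements quality filtering of SILAC
    protein-group tables (contaminant, reverse, single-evidence,
    replicate-occurrence and fold-spread outlier rules), one-sample
    t-testing with Benjamini-Hochberg correction, model-correlation
    clustering of temporal log-ratio trajectories against a fixed set of
    qualitative templates, first-order pulse-chase kinetic decomposition
    into decay rate constants, synthesis rates and half-lives, NanoString
    nCounter transcript processing (background correction, positive
    control QC, geNorm reference selection, geometric-mean normalization,
    fold changes), protein-group-aware dataset alignment, and a
    synthetic-data generator with known ground truth for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
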