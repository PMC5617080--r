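Package: graftquant
Title: Serial-Section Quantification of Intrastriatal Dopaminergic Grafts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies survival and striatal reinnervation of fetal
    dopaminergic grafts in the unilateral 6-OHDA rat model from serial
    histological sections, and relates them to drug-induced rotational
    behavior. Implements truncated-cone (frustum) volume reconstruction from
    per-section areas, Abercrombie-corrected cell counting, optical-density
    normalization against the corpus callosum, thresholded tyrosine-
    hydroxylase fiber segmentation with mirrored contralateral referencing,
    integrated fiber density and dorsoventral outgrowth ratios, rotometry
    processing with balanced group allocation, and the accompanying
    statistical battery (normality-gated t / Mann-Whitney tests, mixed
    repeated-measures ANOVA, regression). A synthetic phantom generator with
    analytic ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    nortest,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'behavior-sim.R'
    'behavior.R'
    'densitometry.R'
    'io.R'
    'morphometry.R'
    'phantom.R'
    'pipeline.R'
    'stats-tests.R'
    'stereology.R'
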