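Package: tonomap
Title: Receptive-Field Complexity and Tonotopic Organization in Primary
    Auditory Cortex
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of frequency receptive fields and tonotopic maps from
    two-photon calcium imaging of primary auditory cortex (A1). Classifies
    frequency response areas (FRAs) into single-peaked, double-peaked and
    complex shapes with a 75-percent-threshold run classifier, computes best
    frequency, bandwidth and Fano factor per neuron, quantifies local best
    frequency variability in octaves and octaves per millimetre, normalizes
    tonotopic scatter across species through hearing-range-derived gradient
    slopes, fits the global tonotopic gradient, and measures pairwise signal
    and noise correlations. Includes a synthetic-cortex generator with known
    ground truth (class labels, best frequencies, shared trial noise,
    neuropil mixing) so every stage of the pipeline is testable without
    recorded data.
License: MIT
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
    withr,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, Neuroscience, SingleCell, Visualization
RoxygenNote: 7.3.3
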