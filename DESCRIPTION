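Package: erptopo
Title: Topographic Analysis of Multichannel Evoked Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Preprocessing and topographic statistics for stimulus-locked
    multichannel EEG evoked potentials (sensory evoked potentials, SEPs).
    Covers zero-phase Butterworth filtering, average referencing, spherical
    spline interpolation of virtual channels, epoching, artifact rejection,
    baseline correction and averaging; automated SEP component marking with
    split-half stability gating and responder rates; data-driven component
    time windows from global field power (GFP) minima and inflection points;
    reference-independent randomization statistics (GFP condition test,
    topographic analysis of variance, topographic consistency test, channel
    t-maps); microstate segmentation by atomize-and-agglomerate hierarchical
    clustering with split-half cross-validated selection of the class count;
    and a seeded synthetic SEP generator that provides ground truth for every
    stage. Reads a subset of the BrainVision recording format and ships a
    config-driven end-to-end pipeline with tidy result tables and ggplot2
    figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
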