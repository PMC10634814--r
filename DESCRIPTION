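Package: dspiker
Title: Detection and Single-Channel Classification of Hippocampal Dentate Spikes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for detecting dentate spikes (DSs) in hippocampal local
    field potentials (LFPs) and classifying them into their two subtypes.
    Provides artifact-robust peak detection (reference subtraction, Tukey
    outlier filtering), delta-state segmentation via empirical mode
    decomposition, waveform-dynamics width metrics based on second-derivative
    concavities, a multichannel current-source-density reference classifier
    (CSDbC), and a single-channel waveform-based classifier (WFbC) built on
    Gaussian mixture clustering of peri-peak waveforms with iterative
    artifact-cluster removal and a dissimilarity-index single-type check.
    Includes a synthetic laminar-LFP generator with ground-truth events so
    the full pipeline can be exercised and validated without recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    tidyr,
    ggplot2,
    generics,
    jsonlite,
    mclust,
    signal
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
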