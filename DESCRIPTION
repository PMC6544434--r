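Package: xmv1
Title: Cross-Modal Auditory-Visual Analysis Toolkit for Mouse V1 Calcium Imaging
Version: 0.1.0
Authors@R:
    person("xmv1", "developers", email = "xmv1-dev@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studying context-dependent
    auditory signaling in mouse primary visual cortex with two-photon calcium
    imaging. Provides a synthetic-data generator with known ground truth
    (GCaMP6s-like fluorescence, neuropil contamination, trial structure, pupil
    trajectories, periodic-stimulus intrinsic-imaging movies), calcium-trace
    preprocessing and temporal deconvolution, saccade-based trial filtering,
    functional cell-type discovery by Ward hierarchical clustering with
    homogeneity pruning and re-aggregation, bespoke bootstrap statistics
    (responder detection, population-distribution partitions, supra-linearity
    label shuffles), Fourier retinotopic phase mapping, and a threshold-linear
    excitatory/inhibitory rate model reproducing context-dependent sign
    switching and bimodal response boosting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    rhdf5,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
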