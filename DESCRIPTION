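Package: ephyskit
Title: Headless Analysis Toolkit for Electrophysiology Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A units-aware object model for electrophysiology data (blocks,
    segments, channel groups, units, spike trains, analog signals, events and
    epochs) together with the machinery needed to analyse it without a GUI:
    self-contained JSON selections over container hierarchies, user-defined
    filter chains with exclusive groups, lazy-loading data providers, an
    analysis-plugin runtime with parameter-keyed HDF5 result caching and three
    execution modes (in-process, subprocess, exported standalone bundle), and
    the standard spike-train and LFP analyses: auto- and cross-correlograms,
    interspike-interval histograms, peristimulus time histograms, kernel spike
    density estimation with data-driven bandwidth optimization, and
    spectrograms. Includes deterministic synthetic-data generators (Poisson and
    stimulus-modulated spike trains, sinusoid-plus-noise signals) so every
    component is testable with known ground truth, plus a small command-line
    interface for inspecting, converting and batch-processing recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    R6,
    jsonlite,
    rhdf5,
    digest,
    signal,
    callr,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
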