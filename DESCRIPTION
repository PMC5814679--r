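Package: avbind
Title: Audio-Visual Temporal Coherence Analysis for Auditory Cortex Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how temporal coherence between an auditory
    amplitude envelope and a visual luminance envelope shapes auditory
    cortical representations. Provides synthesis of amplitude-modulated
    artificial vowel streams with matched luminance envelopes and optional
    timbre deviants, a generative simulator of spiking units and local field
    potential (LFP) sites with controllable coherence-dependent reliability
    and visual phase resets, a Euclidean-distance spike-pattern classifier
    with leave-one-out cross-validation and permutation nulls, the visual
    preference index (VPI), timbre-deviant discrimination, Morlet-wavelet
    inter-trial phase coherence (ITPC), and single- and dual-stream phase
    and power dissimilarity indices with Bonferroni and adjacency
    significance rules, plus an end-to-end pipeline that produces summary
    report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
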