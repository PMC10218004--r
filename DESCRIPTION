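Package: edgetrack
Title: Evoked-Response and Oscillator Models of Neural Phase-Locking to
    Acoustic Edges in Speech
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying how low-frequency
    neural activity phase-aligns to the amplitude envelope of speech.
    Implements two generative models of envelope tracking driven by acoustic
    edges (peakRate events): a coupled-oscillator entrainment model and an
    evoked-response (kernel convolution) model, together with the phase
    statistics that discriminate them: inter-event phase coherence (IEPC),
    cerebro-acoustic coherence (CAC), theoretical uniform-phase baselines,
    2D cluster-based permutation tests, spectral and temporal IEPC profiles,
    magnitude-quantile analyses, and a power-versus-IEPC noise robustness
    sweep.  A synthetic-data module generates event trains with speech-like
    statistics, amplitude-modulated waveforms, evoked-response kernels, and
    MEG-like responses (kernel convolution plus temporal jitter and 1/f
    noise) so the full pipeline is testable without audio corpora or
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    signal,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
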