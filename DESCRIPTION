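Package: epicoh
Title: Spike-Locked Cortical Source Coherence Networks from Dense-Array EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates cortical source waveforms from scalp EEG with oriented
    equivalent-dipole patches on a triangulated cortical surface, using
    minimum-norm or cortical-surface-Laplacian (CSL) regularized least squares,
    and computes spike-locked spectral coherence networks among parcel-averaged
    source waveforms. Provides patch tessellation of cortical meshes with
    per-patch dipole orientations, a discrete surface Laplacian smoothing
    operator, spike-centered epoching into pre-spike, spike, and post-spike
    intervals, cross-spectral coherence matrices per frequency bin and band
    (delta through gamma, 1-70 Hz), top-K coherence edge extraction, and a
    fully synthetic data generator (icosphere meshes, analytic dipole lead
    fields, 1/f background sources with planted coherent pairs and spike
    transients) so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
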