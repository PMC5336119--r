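Package: eitproc
Title: Simulation, Demodulation and Image Reconstruction for Parallel
    Multi-Frequency Electrical Impedance Tomography Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A software pipeline for parallel-electrode electrical impedance
    tomography (EIT) built around amplitude-modulated current injection
    recorded on EEG-style multi-channel amplifiers. Provides a synthetic raw
    recording simulator (switched sinusoidal carriers, coded trigger channel,
    white noise, random-walk drift, anti-aliasing filter gain, dispersive
    tissue impedance and stimulus-locked impedance transients), trigger-channel
    decoding and segmentation, zero-phase band-pass filtering with Hilbert
    envelope demodulation, frame assembly with amplitude-threshold rejection,
    noise/drift/SNR/reciprocity quality metrics, coherent (stimulus-triggered)
    averaging, multi-frequency and frequency-sweep spectroscopy, and a 2D
    finite-element forward model with adjoint sensitivity matrix, zeroth-order
    Tikhonov inversion, cross-validated regularisation and noise-based image
    correction.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
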