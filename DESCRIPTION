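Package: rppgvitals
Title: Camera-Based Heart Rate and Blood Oxygenation from Face Region Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Remote photoplethysmography (rPPG) post-processing: turns
    spatially pooled, per-frame intensity series from five face regions
    (forehead, cheeks, cheeks and nose, lips) in five channels (red, green,
    blue, grey, infrared), together with face-to-camera distance and
    timestamps, into per-window heart rate (BPM) and blood oxygenation
    (SpO2, %). Implements fps-adaptive signal pre-processing (detrending,
    interpolation onto an even grid, Hamming windowing, median filtering,
    FFT upsampling, L2 normalisation), blind source separation (FastICA,
    PCA, PCA followed by ICA, JADE, spectral embedding), FFT magnitude
    spectra with a 0.66-3.33 Hz cardiac bandpass, signal-to-noise-ratio
    based candidate selection across regions and channels, ratiometric
    SpO2 from haemoglobin extinction coefficients, sliding-window
    estimation with a reliability gate, evaluation metrics against a
    per-second ground truth, and a synthetic multi-channel signal
    generator so the whole pipeline is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
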