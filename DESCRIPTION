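Package: fpas
Title: Fast Periodic Auditory Stimulation: Stimulus Construction and
    Frequency-Tagged EEG Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing fast periodic auditory
    stimulation (FPAS) experiments, in which short vocalizations are
    presented at a fixed base rate (2.5 Hz) with a target emotion category
    embedded at every third position (0.833 Hz), tagging category-selective
    brain responses at known frequencies.  The package covers stimulus-level
    audio processing (RMS equalization, onset/offset ramps, spectral centre
    of gravity, pitch, harmonicity-to-noise ratio, Hilbert envelopes, and
    frequency scrambling within fixed spectral windows), sequence assembly
    and rendering, acoustic control analyses (sequence-envelope spectra and
    a gammatone cochlear simulation), synthetic multichannel EEG generation
    with steady-state and transient components embedded in 1/f noise, the
    frequency-domain analysis (harmonic z-scores against local noise bins,
    baseline-subtracted amplitudes, SNR, harmonic summation, intact versus
    scrambled contrasts with Benjamini-Hochberg correction), time-domain
    ERP analysis with a consecutive-significance criterion, and
    signal-detection (d-prime) scoring of the accompanying behavioral tasks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
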