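Package: swaquant
Title: Slow-Wave Activity Quantification for Preclinical Sleep EEG Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end quantification of non-rapid-eye-movement (NREM) sleep
    slow-wave activity from rodent EEG recordings, built for preclinical
    pharmacological intervention studies. Implements artifact-aware EEG
    post-processing (clipping detection, three-point smoothing, Fermi-window
    tapering, resampling to 200 Hz, zero-phase equiripple FIR band-pass
    filtering, and spline reconstruction of brief NREM outliers), Hamming-window
    spectral estimation of 4-s epochs with relative band power normalisation,
    hourly delta-activity gain versus baseline on a Zeitgeber-time axis, and the
    accompanying statistical battery (Welch and Student t-tests with Cohen's d,
    hourly test series with false-discovery-rate correction, two-way ANOVA with
    partial eta squared and pairwise confidence intervals, point-biserial to
    biserial correlation transformation). Also quantifies amyloid plaque burden
    from label masks by the area-fraction fractionator, normalises ELISA
    readouts to tissue mass, and scores forced-alternation T-maze behaviour. A
    seeded synthetic-data generator with known ground truth (state-dependent
    EEG spectra, semi-Markov hypnograms, injected artifacts and treatment
    effects, plaque masks with exact area fractions) makes every stage testable
    without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    car,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
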