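Package: slicecond
Title: Frequency-Dependent Conductivity Estimation from Multielectrode
    Array Slice Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the electrical conductivity of brain
    slice tissue from multielectrode array (MEA) recordings of injected
    sinusoidal currents.  Implements closed-form volume-conductor models
    (homogeneous, saline half-space, and method-of-images for the
    plate-slice-bath geometry), a synthetic session generator with known
    ground truth, phasor extraction with electrode quality control, joint
    estimation of saline conductivity, injection phase, and electrode
    polarization impedance, electrode-polarization-corrected tissue
    conductivity fits, minimum-phase (cepstrum) construction of causal
    complex conductivity spectra, frequency-dependent filtering of
    point-source potentials, and a passive compartmental cell proxy for
    forward modelling of local field potentials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
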