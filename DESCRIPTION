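Package: cvmr
Title: Control-Volume Pressure-Differential Estimation from Phase-Contrast MR
    Velocity Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-invasive estimation of pressure-differential waveforms from
    through-plane phase-contrast magnetic resonance (PC-MR) velocity images
    using integral control-volume mass and momentum conservation. Provides the
    exact Womersley solution for oscillatory pipe flow as ground truth, a
    synthetic PC-MR acquisition generator (pixel rendering, calibrated velocity
    noise, phase wrapping, differential-pressure sensor emulation), magnitude
    based region-of-interest segmentation, discrete estimators for every term
    of the axial momentum balance (inertial, momentum inflow, viscous, body and
    pressure forces), the Urchuk-Plewes per-pixel Navier-Stokes comparator,
    noise-uncertainty propagation, and waveform statistics (phase and ensemble
    averaging, sinusoid fitting, normalized rms deviation) with NIfTI/CSV/JSON
    input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
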