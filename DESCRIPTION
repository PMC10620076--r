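Package: tistim
Title: Temporal Interference Stimulation Dosimetry on Layered Head Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Desk-scale modeling toolkit for transcranial temporal
    interference stimulation (tTIS). Builds voxelized multi-layer spherical
    head phantoms with 10-10 electrode placement and region-of-interest
    masks, solves the ohmic quasistatic potential with a finite-difference
    conjugate-gradient solver under Dirichlet electrode boundary conditions
    and current normalization, computes the maximum modulation envelope
    magnitude of two interfering kilohertz fields, sweeps symmetric
    electrode montages against percentile-threshold focality and activation
    metrics with Pareto-front extraction, synthesizes pulsed theta-burst TI
    waveforms and validates their envelope structure, and produces ROI
    dosimetry reports and histograms. Volumes are read and written as
    NIfTI-1.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
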