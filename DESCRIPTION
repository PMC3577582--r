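Package: fourcurrent
Title: Four-Current Simplified Cardiac Action Potential Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for a semiphysiological four-current cardiac
    action potential model: a Fenton-Karma-type ionic model extended with a
    fast transient outward (Ito-like) current that reproduces the phase-1
    notch of epicardial myocytes. Provides space-clamped single-cell
    dynamics, explicit monodomain reaction-diffusion propagation on 1D
    cables, 2D sheets and 3D voxel geometries with anisotropic fiber
    diffusion, dynamic APD and CV restitution protocols, S1-S2 spiral-wave
    initiation and tip tracking, heart-dipole pseudo-ECG computation on a
    synthetic two-shell ventricle geometry, and Levenberg-Marquardt fitting
    of model parameters to action-potential templates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
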