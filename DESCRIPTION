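Package: mocoMRI
Title: Retrospective Rigid-Motion Correction for 3D Multishot Cartesian MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and retrospective correction of rigid head motion in
    3D multishot Cartesian brain MRI. Generates distributed-incoherent
    (random-checkered) phase-encode sampling orders, simulates
    motion-corrupted multicoil acquisitions through the rigid-motion forward
    model A = M F S C, reconstructs tiny k-space segments, estimates a
    per-segment rigid-motion time series by groupwise registration of the
    segment reconstructions, and produces motion-corrected CG-SENSE
    reconstructions. An alternating image/motion optimizer is included as a
    baseline, together with SSIM/PSNR/NMSE and gauge-invariant trajectory
    error metrics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    Rcpp,
    jsonlite,
    yaml,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
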