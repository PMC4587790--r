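Package: flowbold
Title: Periodic-Design fMRI Analysis of Flow-Motion BOLD Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for block-design (periodic) fMRI
    studies of visual flow-motion selectivity, exercised on synthetic BOLD data
    with known ground truth. Provides a random-dot optic-flow stimulus
    generator with a locally motion-matched random control, simulators for
    task and resting-state 4D BOLD runs, rigid-motion scrubbing with
    half-period cutting, mean-intensity adjustment and Fourier high-pass
    filtering, voxelwise general linear models with gamma hemodynamic response
    functions and cluster thresholding, fixed-effects multi-subject maps with
    false-discovery-rate control, V1-seed lagged-correlation masking, Fourier
    signal-to-noise and response-phase statistics with vectorial group tests,
    and resting-state region-of-interest connectivity with super-subject
    significance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    graphics,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
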