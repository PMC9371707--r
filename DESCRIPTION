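Package: activegel
Title: Active-Gel Mechanics of Epithelial Monolayer Fluidization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuum active-gel modelling and force-inference tools for
    confluent epithelial monolayers exiting quiescence. Solves the coupled
    elastic/actinomyosin transport equations on a disc with P1 finite
    elements and implicit (Newton) time stepping; computes traction forces
    from the substrate friction law; summarises simulations through
    area-weighted radial-velocity statistics, prestress sweeps and sigmoid
    response fits. Also provides the measurement side of the pipeline:
    Fourier-transform traction cytometry (Boussinesq half-space inversion),
    monolayer stress microscopy (force-balance stress recovery), particle
    image velocimetry, kymographs, density/thickness calibration, and
    synthetic data generators with known ground truth for validating every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    stats,
    utils,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
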