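Package: cinemotion
Title: Surrogate-Driven Respiratory Motion Models from 2D Cine-MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating surrogate-driven models of
    respiratory motion from interleaved 2D cine-MR image series, as used in
    MR-guided radiotherapy. The package extracts local (diaphragm, skin) and
    global (principal-component) surrogate signals from a surrogate slice,
    fits linear correspondence models that map the signals to cubic B-spline
    control-point displacements of the internal anatomy over two sliding
    regions, and evaluates the estimated motion against reference motion via
    the deformation field error. A seedable synthetic cine-MR generator with
    known ground-truth sliding motion, breathing variability, hysteresis and
    breath-holds makes the whole pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    EBImage,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    withr
Config/testthat/edition: 3
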