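Package: clotquant
Title: Quantitative Analysis of Fibrin Clot Mechanics, Structure and Lysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for quantifying fibrin clot biophysics in
    plasma-clot studies: nonlinear rheology feature extraction from
    stress-ramp curves (linear modulus, strain-stiffening onset, maximum
    differential modulus, rupture point), steady-state moduli from
    polymerization time series, fiber-network morphometry from binarized
    micrographs (fiber diameter, porosity, pore statistics, intersection
    density), fibrinolysis kinetics from fluorescence-release time courses,
    and covariate-adjusted cohort statistics (Spearman correlations, group
    tests, fibrinogen-adjusted regression). A synthetic-data module
    generates every input with known ground truth for recovery testing and
    calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    minpack.lm,
    EBImage,
    jsonlite,
    yaml,
    png,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff
Config/testthat/edition: 3
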