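Package: duospec
Title: Multivariate Calibration of Two Spectrally Overlapping Drugs from
    UV-Vis Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale chemometric workflow for the simultaneous
    quantification of two spectrally overlapping analytes (montelukast and
    levocetirizine) from UV-Vis absorption spectra. Provides structured
    calibration and validation designs (a five-level cyclic multilevel
    calibration design and stratified Latin hypercube validation sets), a
    Beer-Lambert synthetic spectrum generator, four multivariate calibration
    models (classical least squares with intercept, principal component
    regression, partial least squares, and genetic-algorithm wavelength
    selection feeding PLS), a complete figures-of-merit suite (RMSEC, RMSECV,
    RMSEP, R-squared, Q-squared, SEC, bias, RRMSEP, BCMSEP, LOD, LOQ,
    recovery and precision statistics, one-way ANOVA model comparison), and
    quantitative sustainability calculators (carbon footprint, BAGI blueness,
    RGB12 whiteness).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lhs
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
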