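Package: bipolarLN
Title: Linear-Nonlinear Analysis of Nonlinear Spatial Integration in Retinal
    Bipolar Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the quantitative analysis of graded membrane-potential
    responses of retinal bipolar cells under visual stimulation: rendering of
    spot, grating, white-noise and naturalistic surrogate stimuli in Weber
    contrast; a generative subunit-model simulator of bipolar-cell voltage
    with configurable local nonlinearities, Gaussian center/surround pooling
    and conductance-based light input; trace conditioning (median filtering,
    decimation, high-pass detrending, epoch averaging); estimation and
    cross-validated evaluation of linear-nonlinear (LN) receptive-field
    models by response-weighted averaging and space-time factorization; a
    battery of scalar nonlinearity indices (hyperpolarization, output
    nonlinearity, spatial nonlinearity, sustained-transient, center-surround,
    biphasic); the subunit prediction model for contrast-reversing patterned
    spots; and current-injection analyses of input resistance and
    reversal-potential extrapolation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    signal,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
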