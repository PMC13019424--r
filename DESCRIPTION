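Package: acylquant
Title: Fatty Acyl Group Compositions of Fats from Raman Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Chemometric quantification of fatty acyl group compositions
    (mole percent of myristate, palmitate, stearate, oleate and linoleate)
    in fat mixtures from Raman spectra. Implements preprocessing (background
    subtraction, iterative polynomial baseline correction, ester-band
    normalization), a PCA-based calibration transfer that simulates
    triacylglycerol calibration spectra from fatty acid methyl ester
    spectra, classical and nonnegative least-squares unmixing, NIPALS PLS1
    regression with cross-validated latent-variable and spectral-window
    selection, the standard calibration and prediction error metrics,
    median-linkage clustering of per-sample compositions, and a synthetic
    pseudo-Voigt spectrum generator for fully reproducible end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
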