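Package: spectrakit
Title: Reproducible Preprocessing and Chemometric Analysis of Raman and SERS Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless toolkit for Raman and surface-enhanced Raman (SERS)
    spectral data: a validated spectral container with strict axis semantics,
    text-format I/O (two-column and wide-table), a provenance-recording
    preprocessing pipeline (integer-grid interpolation, cropping, running-median
    despiking, Savitzky-Golay and Fourier smoothing, airPLS / iterative-polynomial
    / Gaussian-Lorentzian baseline correction, area / peak / min-max
    normalization, multi-criterion outlier screening), reproducibility statistics
    (average spectral variation and relative variation), prominence-based peak
    identification, Pearson correlation matrices, Ward hierarchical clustering,
    PCA, and a seeded exact t-SNE embedding, plus a seeded synthetic-spectrum
    generator with stored ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    pracma,
    yaml,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    signal,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
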