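Package: oplsnmr
Title: OPLS-DA Modelling and Preprocessing for 1D 1H-NMR Tissue Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chemometric pipeline for classifying tissue specimens from
    one-dimensional proton NMR spectra. Provides spectral standardization
    (recursive segment-wise peak alignment, fixed-width binning,
    probabilistic quotient normalization), a from-scratch orthogonal
    projections to latent structures (OPLS) regression and discriminant
    model with venetian-blind cross-validation, DModX and Hotelling's T2
    outlier diagnostics, loading-correlation interpretation, a blinded
    train/test workflow with a tissue-age control analysis, and a seeded
    synthetic spectrum generator for benchmarking the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    graphics,
    stats,
    tools,
    utils
Suggests:
    withr,
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
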