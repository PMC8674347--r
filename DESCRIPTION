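Package: ramanmp
Title: Microplastic Detection and Quantification from Raman Hyperspectral Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing pipeline for point-by-point Raman hyperspectral maps of
    filter surfaces used in microplastic analysis of food samples. Provides
    per-pixel spectral preprocessing (spline regridding onto a common
    wavenumber grid, asymmetric-least-squares baseline correction, spline
    smoothing, standard-deviation scaling), random-forest polymer
    classification with out-of-bag error control and low-confidence review
    flags, gap-tolerant spatial clustering of classified pixels into
    particles, and quantification rules (area extrapolation, blank
    subtraction, per-100-mL counts, size fractions, digestion quality
    control, spherical-equivalent mass estimates). A synthetic-data
    generator produces labeled spectra, training libraries and whole filter
    scenes with ground truth so that every pipeline stage can be exercised
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    ranger,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
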