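Package: ramanSC
Title: Depth-Resolved Confocal Raman Analysis of Keratin Conformation and
    Water in the Stratum Corneum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for depth profiling of human stratum corneum by in
    vivo confocal Raman microspectroscopy. Provides tangent-point linear
    baseline correction, PCA-based spectral denoising, a piecewise-linear
    high-wavenumber baseline, constrained multi-Gaussian band deconvolution
    (Amide I and the CH/OH stretching region), the standard keratin
    secondary- and tertiary-structure band ratios (beta-sheet/alpha-helix,
    disulphide conformer fractions, C-S/S-S, buried/exposed tyrosine, CH3
    peak position), water mass percentage and bound-water sub-band analysis,
    skin-surface and stratum corneum thickness estimation with normalization
    to percent depth, and paired cohort statistics. Includes a synthetic
    depth-series generator with full ground truth so that every stage of the
    pipeline can be validated without access to in vivo data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
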