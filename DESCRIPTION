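Package: mitosted
Title: Synthetic STED Imaging and Mitochondrial Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for dual-channel STED/confocal
    imaging of mitochondria. Generates synthetic scenes of tubular
    mitochondrial networks with transverse cristae and mtDNA nucleoids,
    models STED image formation with a saturation-power depletion law,
    estimates saturation power from depletion series and resolution by
    Fourier ring correlation and line-profile FWHM fitting, segments
    cristae and nucleoids, performs skeleton-based morphometry with a
    three-class length/cristae-count rule, and computes nucleoid spatial
    statistics (nearest-distance laws, threshold fractions, area ratios,
    group comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    withr,
    stats,
    utils,
    graphics,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ranger
Config/testthat/edition: 3
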