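Package: topoholes
Title: Topological Quantification of Micro-Hole Microstructure in
    Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the number, size, crowding and arrangement of
    micro-holes (connected low-signal regions) in 2D greyscale microscopy
    images such as second harmonic generation (SHG) or two-photon
    autofluorescence (TPaF) exports. Images are binarized by Otsu's
    method, tiled into patches, transformed with a signed Euclidean
    distance transform (SEDT), and summarised by the persistent homology
    of the resulting cubical sublevel-set filtration. Per-patch panels of
    interpretable persistence statistics (micro-hole counts, inscribed
    radii, inter-hole distances, persistent entropy) feed permutation
    hypothesis tests with Benjamini-Hochberg false-discovery-rate control
    and a support-vector patch classifier. A synthetic binary-image
    generator with planted micro-hole ground truth supports end-to-end
    validation.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    e1071,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    rlang,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
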