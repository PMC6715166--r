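Package: shellmorph
Title: Three-Dimensional Valve Morphometrics for Bivalve Shells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: End-to-end morphometrics of bivalve valves from micro-CT surface
    meshes. Reads STL valve surfaces paired with digitized commissure curves,
    splits valves into interior and exterior surfaces, and computes the
    non-shape traits (signed-tetrahedra shell and internal volumes, shell
    proportion, centroid size, and ornamentation height above the modal
    shell-thickness baseline). Internal shell shape is captured by a
    plane-section semilandmark grid (100 sections x 101 flat-sorted points)
    superimposed by generalized Procrustes analysis of four fixed commissure
    landmarks. Between-fauna comparisons include PCA morphospaces with
    back-projection, sum-of-variances disparity, median minimum-spanning-tree
    distance, cumulative principal-component ranges, label-reshuffling null
    models, Wilcoxon and Kolmogorov-Smirnov tests, and a nine-field
    classification of trait range shifts between regions. Parametric
    synthetic valves with known volumes and implanted ornament support fully
    reproducible testing without scan data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
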