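Package: osteomorph
Title: High-Density 3D Geometric Morphometrics for Size-Independent
    Dimorphism Detection in Long Bones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting size-independent shape
    dimorphism in populations of long bones (femora, tibiae) using
    high-density landmarking: anatomical landmarks plus curve and surface
    sliding semilandmarks, thin-plate-spline relaxation against a template
    and a Procrustes consensus, generalized Procrustes analysis, principal
    component analysis, and per-axis univariate Gaussian mixture modeling
    with BIC model selection.  Includes allometry (size-correlation)
    testing, repeatability quantification, fragment (proximal/distal
    epiphysis) analyses with cluster-consistency accounting, minimum
    number of elements/individuals bookkeeping, readers and writers for
    classic morphometric landmark formats (TPS text, flat tables) and
    triangle meshes (PLY, OBJ, STL), and a synthetic femur-population
    generator for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
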