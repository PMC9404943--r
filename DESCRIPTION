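Package: gelmap2d
Title: Two-Dimensional Electrophoresis Gel Image Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of two-dimensional gel electrophoresis (2DE) scans of
    Coomassie-stained protein gels: impulse-noise smoothing and morphological
    background removal, automatic master-gel selection by scoring vertical
    geometric distortion of iso-molecular-mass rows, spot detection by
    second-order rotational-symmetry filtering with watershed segmentation,
    Laplacian-of-Gaussian curvature filtering and neural region
    classification, landmark-based rigid plus thin-plate-spline gel
    registration with spot pairing, and normalized spot quantification with
    signed fold-changes and isoform share percentages. A ground-truthed
    synthetic gel generator supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
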