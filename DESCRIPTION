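Package: ThymoVasc
Title: Quantification of Thymic Vasculature from Intravital and
    Cleared-Organ Two-Photon Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify microvascular hemodynamics and morphology of
    the thymus from two-photon microscopy. Implements kymograph and red blood
    cell tracking velocimetry on time-lapse movies with negative-contrast
    cells, vessel diameter estimation by perpendicular cross-line full width
    at half maximum, Poiseuille wall shear rate, and Evans-blue leakage
    ratios; and, for optically cleared whole organs, a 3D morphometry chain
    with organ masking, an anisotropy-aware Euclidean distance-map shell,
    seeded random field-of-view sampling, Otsu vessel area fractions and
    vessel frequency. Ground-truthed synthetic phantoms (flow movies and
    cleared volumes) make every stage testable without animal data, and a
    two-group statistics layer (Shapiro-Wilk gated t-test or exact
    Mann-Whitney U) reproduces the irradiated-versus-untreated comparison
    design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    jsonlite,
    tiff,
    ggplot2,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, ImageProcessing, Visualization, CellBiology
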