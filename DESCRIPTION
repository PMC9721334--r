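Package: fibrilSAXS
Title: Cross-Section Analysis of Small-Angle Scattering from Disoriented Fibrils
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for extracting cross-sectional structural information about
    amyloid and other cross-beta fibrils from small-angle X-ray scattering of
    disoriented fibrils in solution or embedded in fixed tissue. Provides
    forward scattering calculators (solid-cylinder transform, Debye formula,
    stacked-layer fibril models), recovery of equatorial intensity from
    isotropic scattering, pair distribution and correlation functions in
    spherical and cross-section geometry by direct quadrature and by
    regularized indirect Fourier transform, scan-grid processing for scanning
    microdiffraction experiments (substrate masking, azimuthal averaging,
    SAXS/WAXS merging, cross-beta heat maps, two-reference background
    subtraction), and synthetic-data generators including 2D liquid-like
    cylinder packings with interparticle interference.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    splines,
    pracma,
    bio3d,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
biocViews: Software, StructuralPrediction, Visualization
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
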