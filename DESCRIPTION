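Package: blockpet
Title: Block-Geometry PET Scanner Modeling and Fully-3D OSEM Reconstruction
Version: 0.1.0
Authors@R:
    person("blockpet", "developers", email = "blockpet@example.org",
           role = c("aut", "cre"))
Description: Models positron emission tomography (PET) scanners whose
    detectors are rectangular crystal blocks arranged on the faces of a
    regular polygonal prism ("blocks-on-cylindrical"), alongside the
    conventional idealized cylindrical scanner model.  Provides exact
    Cartesian detector-position maps with average depth of interaction,
    sinogram bin parameterization and list-mode histogramming, Siddon
    raytracing forward/back projectors with multi-ray tangential sampling,
    fully-3D OSEM reconstruction with normalization and attenuation
    correction, rotating-plane-source normalization factor estimation,
    NEMA NU-4 style image-quality metrics, an analytic synthetic
    acquisition simulator with Poisson counting noise, and interfile-style
    header I/O with a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
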