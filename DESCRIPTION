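Package: swdmorph
Title: Volumetric Morphometrics by Spherical Wave Decomposition and
    Symplectomorphic Registration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Landmark-free geometric morphometrics for 3D image volumes
    (micro-CT, MRI). Decomposes volumetric shapes in a spherical wave basis
    (spherical harmonics times spherical Bessel radial modes), estimates
    shape complexity by least-squares model-order selection, segments
    volumes from the analytic derivatives of the decomposition with
    spatial-coherence filtering, registers specimens with a symplectic
    phase-space integrator regularized by a Gaussian coupling kernel,
    builds groupwise templates, and compares specimens with
    posture-factored morphological distances and minimum spanning trees.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    tiff,
    jsonlite,
    pracma,
    igraph,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape
Config/testthat/edition: 3
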