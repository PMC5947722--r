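Package: diffusekit
Title: Diffuse X-Ray Scattering from Crystalline Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for computing and analysing diffuse X-ray scattering from
    ensembles of crystalline atomic models. Builds toy tetragonal crystals and
    supercells, samples ensembles under several displacement models
    (independent Gaussian, liquid-like correlated, rigid-body, two-state loop
    flips), computes per-snapshot structure factors by direct summation,
    accumulates diffuse intensity as the ensemble variance of the structure
    factor (Guinier's equation), decomposes maps into isotropic and
    anisotropic components, enforces Laue symmetry, processes and simulates
    rotation-series detector images (mode filtering, polarization/solid-angle
    correction, pixel-to-Miller-index mapping, integration onto half-integer
    lattices), transforms anisotropic intensities into Patterson maps, and
    decomposes ensemble motion into optimal rigid rotations with Euler-angle
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
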