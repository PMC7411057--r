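Package: darkfieldr
Title: Spectral X-Ray Dark-Field Signals and Structural Size Measures of
    Porous Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Links grating-based spectral X-ray dark-field (XDF) imaging to
    structural size measures of porous two-phase media. Provides seeded 3D
    phantom generators (solid-sphere, hollow-microsphere and Voronoi-wall
    foam structures with a microCT-like degradation model), the projected
    real-space autocorrelation function G(xi) of a volume computed by FFT,
    spectrum-weighted autocorrelation lengths for a Talbot-Lau
    interferometer with a photon-counting detector, the dark-field forward
    model -ln D = sigma*t*(1 - G(xi)) with phase-stepping simulation and
    visibility retrieval, and mean chord length stereology with isotropic
    uniform random test lines. A pipeline correlates the low/high energy-bin
    dark-field quotient with mean chord length across synthetic materials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
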