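Package: fbmland
Title: Neutral Landscape Models by Spectral Synthesis of Fractional
    Brownian Motion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates N-dimensional fractional-Brownian-motion neutral
    landscapes by spectral synthesis, generating Fourier coefficients under
    the fBm spectral-density condition and enforcing the conjugate-symmetry
    constraint required for a purely real inverse transform, so that the
    diagonal-anisotropy artefact of the classic unconstrained generator is
    removed.  Also provides the classic binary neutral models (random
    percolation, hierarchical curdling, rank thresholding), directional
    Moran's I correlograms on a torus with permutation significance for
    anisotropy testing, a replicated Monte Carlo anisotropy experiment with
    McGill notch summaries, dimension-specific Hurst exponents for
    spatio-temporal landscapes, gradient composition, cropping, and grid
    serialisation with a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    optparse,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
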