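Package: actispec
Title: Heterologous Action Spectroscopy Analysis for Opsins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for heterologous action spectroscopy (HAS) of
    visual pigments: baseline normalization and amplitude extraction from
    luminescence time series of opsin-expressing cells, sigmoid
    intensity-response (Hill) curve fitting and inversion to equivalent photon
    fluxes, relative spectral sensitivity computation, and lambda-max
    estimation by least-squares fitting of the Govardovskii A1 visual pigment
    template with a residual-sum-of-squares profile. Includes sequence-level
    opsin feature checks (chromophore-binding lysine and counterion sites in
    bovine rhodopsin numbering) and a synthetic assay generator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    minpack.lm,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
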