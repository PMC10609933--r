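Package: isgrelease
Title: Mechanistic Modelling of Drug Release from In Situ Forming Gels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mechanistic analysis of drug release from injectable in
    situ forming gel (ISG) depots, built around the cup-method dissolution
    assay used for periodontal formulations. Provides a closed-form
    first-order exterior-transfer release model with parameter sweeps, a
    synthetic cup-method data generator with sampling-volume correction and
    configurable measurement noise, finite-difference differentiation
    operators at orders O(h) and O(h^4), least-squares estimation of the
    exterior transfer coefficient and matrix-edge plateau concentration from
    release time series, goodness-of-fit diagnostics, and a forward
    finite-volume simulator of spherical three-phase diffusion (liquid core,
    porous polymer matrix, well-mixed exterior bath) validated against the
    classical series solution for diffusion in a sphere.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
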