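Package: artwall
Title: Opening-Angle Residual Stress and Dissection Initiation in
    Two-Layer Arteries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analytical mechanics of a residually-stressed two-layer
    artery under plane strain. Implements the incompressible
    Holzapfel-Gasser-Ogden fibre-reinforced hyperelastic law for media
    and adventitia, the opening-angle construction of residual stress
    (forward closing of a stress-free open sector and inverse recovery
    of the open sector from the unloaded ring), pressurised inflation
    of the intact residually-stressed annulus, a linear cohesive
    traction-separation law with damage bookkeeping, and a maximum
    principal stress criterion for the initiation of an arterial
    dissection. The boundary-value problems reduce to one nonlinear
    integral equation per configuration, solved by safeguarded
    bracketing with per-layer Gauss-Legendre quadrature.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
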