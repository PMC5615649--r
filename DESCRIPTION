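Package: vesselgrow
Title: Constrained-Mixture Volumetric Growth and Remodeling of the Vessel Wall
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates growth and remodeling of the arterial wall as a
    constrained mixture of elastin, ground matrix and two collagen fiber
    families. Constituent deposition preserves either constituent density
    (CCD) or constituent volume (CCV); the resulting tissue volume change
    drives isotropic (IVG), in-plane (PVG), in-thickness (TVG) or no (NVG)
    volume-growth kinematics through a multiplicative split of the
    deformation gradient. The wall is quasi-incompressible and
    hyperelastic, with exponential collagen fibers that engage beyond a
    recruitment stretch and turn over in response to a stretch-based
    stimulus. Includes a closed-form equi-biaxial patch model and a
    reduced thick-walled two-layer cylinder model of abdominal aortic
    aneurysm evolution, with study drivers sweeping collagen net-growth
    rate and initial constituent volume fractions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
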