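Package: mmwdosim
Title: Millimeter-Wave Skin Dosimetry for Layered Tissue Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical dosimetry of millimeter-wave (6-100 GHz) exposure of
    layered skin models. Solves the normal-incidence plane-wave problem
    through a stack of lossy tissue slabs (transfer-matrix method with
    Cole-Cole tissue dielectric dispersion), computes the absorbed power
    density and specific-absorption-rate depth profile, and obtains the
    steady-state temperature elevation from a closed-form solution of the
    one-dimensional Pennes bioheat equation with a convective surface
    boundary and a core-temperature clamp. Ships precise rat head, rat
    dorsal and human forearm layer stacks, a stochastic thickness sampler,
    an independent finite-difference bioheat solver for verification, and
    derived dosimetric metrics: transmittance, heating factor, thermal
    resistance, depth tables, frequency and blood-perfusion sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
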