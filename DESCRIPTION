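Package: capflux
Title: Blood Flow and Oxygen Transfer in Feto-Placental Capillaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models oxygen transfer from maternal to fetal blood in the
    capillaries of placental terminal villi. Provides a reduced-order
    scaling framework (Poiseuille resistance, Graetz-Leveque and
    equilibrated transfer regimes, a diffusion-limited annular bound, and
    a regression equation with a villous-volume correction), a
    finite-element solver for steady Stokes flow and hemoglobin-enhanced
    advection-diffusion in an axisymmetric capillary with a localized
    dilation, a constrained shape optimizer that finds the dilation
    maximizing oxygen transfer at fixed pressure drop, and tools for
    quantifying dilations from skeleton radius-vs-arclength profiles.
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
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
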