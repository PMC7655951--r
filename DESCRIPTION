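Package: nspefsim
Title: Nonlinear Dispersive Cell Model for Nanosecond Pulsed Electric Field Microdosimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the transmembrane potential, pore density and membrane
    conductivity of a double-shelled spherical cell exposed to nanosecond
    trapezoidal pulsed electric fields. Both membranes carry second-order Debye
    dielectric dispersion integrated in the time domain through the polarization
    vector, and the plasma membrane electroporates according to the asymptotic
    Smoluchowski pore-density equation. The quasi-static field problem is solved
    on an axisymmetric spherical finite-volume mesh with geometrically resolved
    10-nm membranes; closed-form shelled-sphere responses (first- and
    second-order Schwan) are included as verification oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
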