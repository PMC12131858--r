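Package: hfimdesign
Title: Design, Simulation and Validation of Hollow-Fiber Infection Model
    Pharmacokinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to drive a hollow-fiber infection model (HFIM) so that it
    reproduces mono-compartmental pharmacokinetics with a first-order
    absorption phase (site-of-action profiles such as cerebrospinal fluid)
    or intravenous-infusion profiles. Converts target PK parameters into
    quantized ambulatory-pump programs that approximate first-order
    absorption by a series of piecewise-constant infusions, sizes the
    dilution (elimination) pump, forward-simulates the tri-compartmental
    physical rig (central reservoir, intracapillary and extracapillary
    space), estimates the fiber diffusion flow rate from observed
    concentration-time data, and runs prediction-interval and PK-parameter
    bias validation checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    Matrix,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
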