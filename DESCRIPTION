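Package: vestress
Title: Membrane Stress Analysis of the Vestibular Labyrinth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Thin-shell membrane-stress analysis for the pressurized chambers
    of the inner-ear membranous labyrinth. Computes ellipsoid-of-revolution
    shape coefficients, geometric stress factors (s * r / w), hoop and
    meridional stress profiles, toroidal corrections for semicircular canals,
    and pressure-free normalized hoop stresses across chambers. Ships the
    published toadfish (Opsanus tau) morphometric measurements as a built-in
    data set, a CSV/JSON data model for chamber morphometry, and a seeded
    generator of synthetic morphometry cohorts for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
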