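Package: pfcaerosol
Title: Lagrangian Droplet Transport and Size Statistics for
    Catheter-Generated Perfluorocarbon Aerosols
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Desk-scale model of the aerosol produced by an intracorporeal
    inhalation catheter delivering perfluorocarbon liquids (perfluorodecalin
    and FC75) for surfactant-replacement therapy in preterm infants.
    Provides a calibrated surrogate turbulent round-jet carrier field, a
    Lagrangian droplet-parcel solver with Schiller-Naumann drag and
    eddy-interaction turbulent dispersion, Taylor Analogy Breakup (TAB)
    secondary atomization with Rosin-Rammler child sizing, aerodynamic
    particle sizing statistics (MMAD, GSD, aerodynamic/geometric diameter
    conversion, cumulative mass distributions, aerosolization rate), a
    synthetic aerodynamic-particle-sizer sample generator, and a
    Richardson-extrapolation / grid-convergence-index solution-verification
    toolkit.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
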