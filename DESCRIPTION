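Package: cryotherm
Title: Thermal Analysis of Tissue Freezing During Cryoablation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the thermal events of tissue cryoablation.
    Provides the Neumann analytical solution of the one-dimensional two-phase
    Stefan (freezing-front) problem for semi-infinite tissue held at a constant
    ablative surface temperature, together with an independent finite-difference
    enthalpy-method verifier; a differential scanning calorimetry (DSC)
    processing pipeline that extracts specific heat capacity, ice-onset
    temperature, baseline, equivalent specific latent heat capacity, latent
    heat and end-transition temperature from cooling thermograms; statistical
    relations linking latent heat to tissue water content and ice onset to the
    logarithm of the cooling rate; and a seeded synthetic-data generator that
    emulates constant-cooling-rate DSC runs with supercooling and recalescence
    so that every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
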