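Package: shelfkin
Title: Kinetic and Arrhenius Shelf-Life Modelling for Ready-to-Eat Foods
Version: 0.1.0
Authors@R:
    person("shelfkin", "maintainers", email = "shelfkin@example.org", role = c("aut", "cre"))
Description: Fits zero-, first- and second-order reaction-kinetic models to
    spoilage-indicator time series (total volatile base nitrogen, total viable
    count, acid value, instrumental texture) measured at several storage
    temperatures, selects the best reaction order by summed R-squared, regresses
    the fitted rate constants on reciprocal absolute temperature to obtain
    Arrhenius activation energies and pre-exponential factors, and inverts the
    resulting models into time-to-critical-limit shelf-life predictions with
    validation against measured series. Includes a seeded synthetic-trajectory
    generator and parameter-recovery harness so the whole pipeline is testable
    without external data, plus a command-line interface.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
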