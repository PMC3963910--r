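Package: thermotactics
Title: Behavioural Thermoregulation Tactics from Fish Telemetry Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse behavioural thermoregulation in lake fish from
    thermo-sensitive telemetry. Decomposes hourly body-temperature series on a
    basis of sinusoidal temporal eigenfunctions, filtered by Moran's I and
    collinearity (VIF), into a partial adjusted-R2 scalogram; classifies
    individuals into thermoregulatory tactics by PCA of Hellinger-transformed
    scale-band totals; detects epilimnion and metalimnion boundaries from
    thermograph profiles; and models daily excursion frequencies with a
    least-squares regression tree featuring unit-blocked cross-validation,
    1-SE pruning and a permutation test of explained variance. A synthetic-data
    module generates stratified lake profiles, periodic body-temperature series
    and telemetry fixes so that every stage of the pipeline can be exercised
    and validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
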