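Package: dendrosri
Title: Stem Radial Increment and Growth-Climate Response from Automated Point Dendrometers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes half-hourly point-dendrometer and weather-station records
    from a tropical treeline monitoring setting into daily stem radial increment
    (SRI) series and monthly bootstrapped growth-climate response tables. Includes
    a synthetic-data generator emulating a North American Monsoon climate regime
    and the diel stem-size cycle of high-elevation pines, half-hourly logger
    ingest with quality flags, daily weather summaries with derived vapor
    pressure deficit, SRI extraction with spurious-jump screening, and monthly
    bootstrap correlation and principal component regression with a
    percentile-spread significance rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
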