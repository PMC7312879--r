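Package: greyrisk
Title: Grey-System Forecasting and Risk Analysis of Fatal Industrial Accidents
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Tools for surveillance and forecasting of fatal occupational
    accidents with grey system theory. Implements the GM(1,1) grey model
    (first-order accumulating generation, background values, least-squares
    estimation of the developing coefficient and grey input, restored
    exponential prediction, relative-error accuracy testing), grey interval
    prediction for irregularly fluctuating annual series, grey catastrophe
    (disaster) prediction of the timing of future severe accidents, linear
    and quadratic regression baselines, accident-grade classification and
    descriptive tallies for accident record tables, a qualitative bow-tie
    risk structure with JSON and DOT export, and reproducible synthetic
    accident-record generators. Ships the annual death series and severe
    accident dates for the Chinese metallurgical industry, 2001-2017, as
    worked fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
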