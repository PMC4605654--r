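Package: respdeconv
Title: Recovery of Instantaneous Gas-Exchange Signals from Flow-Through
    Respirometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Flow-through respirometry chambers low-pass filter the gas
    exchange signal an animal emits: washout smears short CO2 bursts before
    they reach the analyzer. This package recovers the instantaneous signal
    from recorded concentration traces. It implements the classic
    Z-transform (Bartholomew) correction, an extended method based on a
    gamma-shaped impulse-response model recovering the input from weighted
    derivatives of the data, and a generalized method that calibrates a
    finite-impulse-response inverse filter by least squares. It also
    provides a forward chamber simulator (well-mixed ODE and general LTI
    convolution), impulse-response fitting by ITAE minimization,
    noise-robust differentiation with adaptive filtering, ITAE-based method
    evaluation, and open/closed spiracle phase classification from
    recovered CO2 release rates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
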