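Package: cgmpulse
Title: Minimal-Model Analysis of Continuous Glucose Monitoring Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing continuous glucose monitoring (CGM) records
    in type 2 diabetes with a minimal glucose-insulin model driven by
    impulsive meal inputs. Couples a two-compartment stomach/gut absorption
    cascade to the fast glucose-insulin subsystem of the Topp model,
    personalises the model to an individual record by least-squares fitting
    anchored on isolated liquid-meal pulses, reconstructs the unmeasured
    insulin time series with an exponentially convergent state observer,
    recovers the rate of appearance of glucose due to food with an input
    observer built on smoothing-spline derivatives, and characterises the
    circadian structure of multi-day records with a tapered periodogram.
    Includes a synthetic CGM generator with full ground truth for validating
    fits and observers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    purrr,
    knitr
Config/testthat/edition: 3
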