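Package: spirped
Title: Parent-Metabolite Population PK Simulation and Pediatric Trial
    Design for a Spironolactone Oral Suspension
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the joint pharmacokinetics of spironolactone and its
    active metabolite canrenone after oral suspension dosing, using a linear
    two-compartment parent plus two-compartment metabolite model with
    first-order absorption and lag.  Adult population parameters are bridged
    to children (2 to <17 years) by fixed-exponent allometric scaling, and
    cirrhosis and high-fat-meal effects are applied as multiplicative
    parameter modifiers.  Tools are provided for Monte Carlo dose selection
    against adult reference exposures (noncompartmental AUC metrics and
    prediction-interval comparisons), for windowed sparse PK sampling
    designs, and for design evaluation by first-order population Fisher
    information and simulation/re-estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
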