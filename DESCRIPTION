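Package: fusionsim
Title: Evolution of Identity Fusion and Cooperation Under Indirect
    Reciprocity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Agent-based simulation of the coevolution of identity fusion
    toward a group and cooperation sustained by indirect reciprocity.
    Agents play a one-shot donation game under the standing assessment
    norm, carry a personal reputation that is blended with a shared group
    reputation in proportion to their fusion level, and may ostracise
    perceived hypocrites -- fused peers who contribute less to the group
    reputation than the observer -- at the interaction stage, the
    reproduction stage, or both. Includes a compiled simulation engine, a
    reference engine in pure R that reproduces the identical random draw
    sequence, parameter sweeps over in-group mixing, fusion thresholds,
    perception and execution errors and differential donation costs, and
    brute-force oracles for validating the encounter mechanics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
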