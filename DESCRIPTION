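Package: patlakr
Title: Blood-Brain Barrier Tracer Kinetics by Multiple-Time Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-terminal-timepoint dual-tracer blood-brain
    barrier (BBB) permeability studies in rodents. Implements the Patlak
    multiple-time regression analysis on the exposure-time axis, yielding the
    unidirectional influx constant Ki (uL/g-min) and the reversible vascular
    binding Vi (uL/g) per brain region, with vascular-space correction by a
    co-injected albumin marker, log-linear serum clearance and half-life
    estimation, whole-brain aggregation, equality-of-regression-lines tests,
    two-way ANOVA with Sidak post hoc comparisons, a study CSV schema with
    readers and writers, a command-line interface, and a two-compartment
    forward simulator with known ground truth for validation by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
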