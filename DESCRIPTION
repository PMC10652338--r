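Package: cocmatrix
Title: Quantitative Analysis of Cumulus-Oocyte Complex Matrix Biology
Version: 0.1.0
Authors@R:
    person("COC Matrix", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis toolkit for cumulus-oocyte complex (COC)
    extracellular-matrix biology: solid-state nanopore sizing of hyaluronan
    (event detection, event-area to molecular-weight calibration,
    polydispersity summaries), particle-exclusion-assay porosity and
    HA-binding-protein intensity quantification from multi-channel COC
    images, cumulus-expansion morphokinetics (hourly and 4-hour velocity
    profiles, pre/post difference-between-differences endpoints),
    customized RT2 array 2^-ddCt fold-change analysis with housekeeping-gene
    normalization and regulation calls, and the accompanying statistical
    procedures (normality-gated two-group tests, nested cluster-level
    t-test, Box-Cox transformation, one-way ANOVA with Tukey letters,
    categorical tests, four-parameter logistic calibration). A synthetic
    data module generates every input with known ground truth so the full
    pipeline is testable end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
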