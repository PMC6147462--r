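Package: neurotracer
Title: Dual-Tracer 13C Brain Metabolism and Hippocampal LTP Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of dual-tracer ([1-13C]glucose + [1,2-13C]acetate)
    brain metabolic labeling experiments: isotopomer pattern parsing and
    tabular I/O, standard-curve quantification of 13C NMR peak areas,
    fractional enrichment against HPLC total pools, neuron/astrocyte
    metabolic ratios (glucose and acetate cycling ratios, acetate-versus-
    glucose utilization indices, glycolytic index), group comparison with
    percent change and two-sample t-tests, and field-EPSP/LTP
    electrophysiology quantification. Includes a discrete-turn
    two-compartment (neuron/astrocyte) TCA-cycle label-propagation
    simulator with succinate-stage carbon scrambling that generates
    synthetic isotopomer tables, peak tables, and LTP recordings for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
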