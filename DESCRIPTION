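Package: vegfrsim
Title: Structure-Based Simulation of VEGF Receptor-Adapter Signaling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mass-action ordinary differential equation models of VEGFR1 and
    VEGFR2 signaling through SH2-domain adapter proteins. Builds reaction
    networks in which adapters either compete for a single nonspecific
    phospho-tyrosine site or bind physiologically specific tyrosine sites
    subject to steric co-occupancy constraints derived from adapter crystal
    structure sizes and inter-site distances along the receptor carboxy
    terminus. Simulates adapter phosphorylation time courses, maps them to
    migration, proliferation and degradation cell responses via calibrated
    weights, predicts the effect of adapter-targeted inhibitors, and
    propagates parameter uncertainty with concentration sweeps and Monte
    Carlo sampling. Includes chi-square goodness-of-fit scoring against
    measured phospho/total protein time courses and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
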