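Package: CFScreenSim
Title: Simulation and Evaluation of a Three-Tier IRT-DNA-IRT Newborn
    Screening Algorithm for Cystic Fibrosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to simulate and evaluate a three-tier newborn screening
    algorithm for cystic fibrosis of the kind run in British Columbia:
    immunoreactive trypsinogen (IRT) percentile triage on the first
    bloodspot, a CFTR mutation panel on the daily top fraction, and a
    repeat IRT at day 21 for mutation heterozygotes and fail-safe cases.
    Provides a synthetic birth-cohort generator with Hardy-Weinberg CFTR
    genotypes and calibrated status-conditional biomarker distributions,
    the screening decision engine with an IRT-DNA comparator, consensus
    CF/CFSPID case classification from sweat chloride and genotype, and a
    performance evaluator (PPV, NPV, sensitivity, false-negative rate,
    birth incidence, sweat tests avoided) that also recomputes a bundled
    set of published program counts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    parallel,
    stats,
    tools,
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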