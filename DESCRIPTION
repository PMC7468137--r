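Package: hawkfs
Title: Chaotic Harris Hawks and Cuckoo Search Hybrid for Wrapper Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the CHHO-CS hybrid metaheuristic: Harris hawks
    optimization whose escape-energy schedule is driven by chaotic maps and
    whose guiding positions are refined each iteration by a cuckoo-search
    generation with Levy-flight proposals. The hybrid (and the standalone HHO
    and cuckoo-search optimizers) power a wrapper feature-selection toolkit
    for descriptor/feature tables, scoring candidate subsets with a
    support-vector-machine classifier under a weighted accuracy-plus-sparsity
    objective. Includes a synthetic descriptor-table generator with known
    informative columns, a seeded multi-run benchmark harness with
    mean/std/best/worst summaries, classification-metric tables, and
    convergence-trace export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
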