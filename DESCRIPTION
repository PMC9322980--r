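Package: comorbidARM
Title: Association Rule Mining of Comorbidities in Hospital Discharge Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying comorbidity structure in ICD-10-coded
    hospital-discharge registries of cancer patients. Provides ICD-10/ICD-9-CM
    code-range phenotyping, prevalence tables with chi-squared tests and
    Bonferroni correction, a from-scratch Apriori frequent-itemset miner with
    support/confidence/lift and interest-support (IS) rule ranking, logistic
    models of in-hospital mortality with odds-ratio reporting and forest
    plots, rule-network graph export, and a synthetic discharge-cohort
    generator with plantable pairwise lifts and a configurable logistic death
    mechanism so the whole pipeline is testable without restricted registry
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    yaml,
    jsonlite,
    igraph,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
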