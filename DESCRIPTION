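Package: a2aqsar
Title: Descriptor-Based QSAR and Screening Analytics for Adenosine A2A
    Receptor Agonists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ligand-based modeling of adenosine A2A receptor
    agonist potency: activity-unit conversions (EC50 to pEC50, Ki to
    binding free energy), Pearson-correlation descriptor selection with
    autoscaling, best-subset multiple linear regression with the field's
    standard fit statistics (r, r2, adjusted r2, SEE, F), internal and
    external validation, activity classification of virtual-screening
    hits, a geometric pharmacophore matcher with ranked-screen recovery
    metrics, MM/GBSA energy aggregation identities with hydrogen-bond
    occupancy criteria, and synthetic-data generators that emulate each
    input so the whole pipeline is testable offline. Ships the curated
    agonist training, test and screening tables as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
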