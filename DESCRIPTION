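Package: cvoflow
Title: Ultrasound Quantification of Cerebral Venous Outflow and Collateral Drainage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts per-vessel echo colour Doppler measurements of the neck
    arteries and veins into volumetric flows with propagated insonation-angle
    uncertainty, solves a conservation-based model of the cervical venous
    collateral network, and derives four normalized drainage indexes (DCVO,
    DJVDI, CFI, CCDI) that quantify how much of the head blood inflow returns
    through the internal jugular veins versus collateral routes. Includes
    nonparametric two-cohort comparison (exact Mann-Whitney), Table-style
    cohort summaries, and a seeded synthetic-cohort generator emulating
    healthy-control and chronic cerebrospinal venous insufficiency (CCSVI)
    phenotypes for end-to-end pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
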