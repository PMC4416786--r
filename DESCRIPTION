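Package: kpuu
Title: Brain-to-Plasma Partitioning, Unbound Partition Coefficients and
    Targeted Transporter Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the extent of drug transport across the
    blood-brain barrier in transporter-knockout and humanized mouse models.
    Computes total brain-to-plasma partition coefficients (Kp) with residual
    blood-volume correction, combines them with the unbound volume of
    distribution in brain (Vu,brain, brain-slice assay) and the fraction
    unbound in plasma (fu,plasma, equilibrium dialysis) into the unbound
    partition coefficient Kp,uu, and processes selected/multiple reaction
    monitoring (SRM/MRM) transition tables into absolute transporter
    protein levels with limit-of-quantification censoring and censored
    fold changes.  Includes a synthetic-cohort generator emulating the
    assay designs so the whole chain is testable and parameter-recoverable
    without external data, plus an end-to-end pipeline with schema
    validation and report emission.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
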