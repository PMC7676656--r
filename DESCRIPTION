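Package: panelTMB
Title: Mechanistic Modelling of Tumor Mutational Burden Measured by Targeted Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A simulation and analysis toolkit for tumor mutational burden (TMB)
    as measured by targeted sequencing panels. Models histology-specific true-TMB
    distributions by kernel density estimation, panel sampling noise as a
    discretized Gaussian-plus-Poisson measurement process, and treatment response
    as step, two-level or incomplete-gamma functions of true TMB. From these
    components it computes expected overall response rates, treated fractions,
    diagnostic concordance metrics (PPA/NPA/OPA/PPV/NPV), panel-versus-exome
    regression artifacts, and threshold harmonization diagnostics, including the
    impossibility of matching both treated fraction and response rate across
    assays with different noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
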