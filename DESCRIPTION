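Package: medsyn
Title: Median-Effect Dose-Effect Analysis and Drug-Combination Synergy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduces colorimetric enzyme-inhibition assay absorbances to
    fractional inhibition, fits the mass-action median-effect model
    fa/fu = (D/Dm)^m to single agents and binary mixtures by log-linear
    regression, designs effect-matched binary combinations, and quantifies
    drug-drug interaction with the combination index (CI), dose-reduction
    index (DRI), fa-CI curves and (normalized) isobolograms. Includes a
    synthetic dose-effect and Loewe-additive mixture generator with known
    ground truth for end-to-end validation, and a report builder that
    mirrors the classic single-agent and per-effect-level combination
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
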