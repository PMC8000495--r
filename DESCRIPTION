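Package: estroscreen
Title: Anti-Estrogen Discovery Screen Analysis Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for a fluorescence-polarization based
    anti-estrogen drug-repurposing screen against estrogen receptor alpha
    and its downstream cell-based validation cascade. Provides plate-level
    quality control (Z' factor), robust Z-score hit calling, staged
    annotation triage, multi-assay consensus voting across cell lines,
    four-parameter logistic dose-response and Ki estimation with bootstrap
    confidence intervals, drug-combination synergy surfaces under Loewe,
    Bliss and highest-single-agent reference models, and delta-delta-Ct
    qPCR gene-panel modulation summaries. A synthetic-data generator with
    planted ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
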