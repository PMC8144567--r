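Package: npcpgx
Title: Integrative Pharmacogenomics Pipeline for Nasopharyngeal Carcinoma Organoid Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Re-implements, as a tested analysis pipeline exercisable on
    synthetic cohorts, the bespoke computations of an integrative
    nasopharyngeal carcinoma (NPC) organoid pharmacogenomics study:
    dose-response IC50 extraction with range-censoring proxies,
    Bliss-independence chemoradiotherapy synergy calling, multi-caller
    somatic variant consensus filtering with 96-context mutational
    catalog refitting, two-method differential-expression overlap
    signatures, and ssGSEA-based drug-response classification evaluated
    by ROC/AUC against a random-signature null. Includes synthetic-data
    generators with recorded ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
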