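Package: nutriconcord
Title: Concordance of Nutri-Score, NOVA and Chilean Warning-Label Food
    Classifications
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Deterministic implementations of three front-of-package food
    classification systems -- the Nutri-Score nutrient-profiling score and
    A-E bands, a rule-ladder NOVA processing classifier driven by
    ingredient-marker tags, and the Chilean "high in" warning-label
    thresholds of Law 20.606 -- over a shared per-100 g/100 mL food-record
    model, together with the concordance layer used to compare them:
    frequency distributions by food group, pairwise cross-tabulations with
    row percentages, recommended/not-recommended agreement (including
    Cohen's kappa), and PCA ordination of the ordinally encoded verdicts.
    A synthetic basket generator emulates the 736-item Chilean basic-basket
    product list so the full pipeline can be exercised end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    caret,
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
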