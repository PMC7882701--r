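Package: ddgpath
Title: Protein Stability Perturbation as a Pathogenicity Signal Across
    Gene Inheritance Modes
Version: 0.1.0
Authors@R:
    person("ddgpath", "developers", email = "ddgpath@example.org",
           role = c("aut", "cre"))
Description: Evaluates absolute protein stability change (|ddG|, kcal/mol)
    predicted by computational stability predictors as a score for missense
    variant pathogenicity. Implements balanced-resampling ROC AUC (global,
    per gene, and per inheritance-mode gene group with complements),
    consensus pseudo-predictors averaging member |ddG| values, a
    destabilizing-only filter, Mann-Whitney group-versus-complement
    comparisons, precision-versus-threshold enrichment curves with a
    threshold finder, a synthetic variant-dataset generator with
    inheritance-mode structure, and a command-line pipeline producing
    tabular reports and figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    ggplot2,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
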