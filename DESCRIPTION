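Package: prspredict
Title: Model-Free Sex-Stratified Allelic Polygenic Risk Scores
Version: 0.1.0
Authors@R: person("PRS", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quality control, odds-ratio-ranked variant selection, allelic
    polygenic risk scoring, percentile-threshold phenotype classification,
    leave-one-out cross-validation, smoothed ROC curves, and a Monte-Carlo
    replication test for the overlap of top-variant lists between two
    independent case-control datasets (for example, males and females
    analysed separately). Includes a synthetic cohort generator with
    sex-specific planted allelic effects, readers and writers for PLINK 1
    binary (bed/bim/fam) and a plain-text genotype dialect, and a
    subcommand-style command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
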