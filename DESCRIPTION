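Package: pairRisk
Title: Gene-Pair Risk Scores for Survival Prognosis in Expression Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates rank-based gene-pair prognostic signatures for
    diffuse large B-cell lymphoma (DLBCL) expression cohorts. Screens prognostic
    genes by median-dichotomized univariable Cox, log-rank and Gehan-Wilcoxon
    tests across two training cohorts, forms binary gene-pair order indicators
    on quantile-transformed expression, screens pairs by hazard ratio, and sums
    the surviving pair indicators into an integer risk score. Includes
    empirical-Bayes batch integration, Kaplan-Meier and time-dependent ROC
    evaluation, comparison against coefficient-based signatures by ranked AUC,
    drug-sensitivity stratification of cell-line panels, and a synthetic-cohort
    generator with planted prognostic genes and pairs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    sva
Config/testthat/edition: 3
RoxygenNote: 7.3.3
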