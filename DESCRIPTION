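Package: glycofeed
Title: Fed-Batch Feeding Strategies, CHO Culture Kinetics and Antibody
    N-Glycosylation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for fed-batch CHO bioprocess studies of
    monoclonal antibody N-glycosylation. Computes cell-specific rates
    (growth, glucose, lactate, productivity) from daily culture time
    courses, parses paired Fc glycoform nomenclature, derives
    galactosylation and glycation indices, corrects the intact-level
    hexosylation bias using deglycosylated-mAb glycation profiles, and
    performs compositional statistics on centered log-ratio transformed
    glycan abundances: PCA, Spearman sample correlations, PERMANOVA with
    sequential sums of squares, multivariate dispersion homogeneity,
    moderated linear-model contrasts with FDR control, and gated
    parametric/non-parametric group comparisons. Includes a seeded
    fed-batch simulator of seven feeding strategies with known
    ground-truth parameters for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    pracma,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    limma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
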