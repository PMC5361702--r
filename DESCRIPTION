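Package: metapeak
Title: End-to-End Statistical Processing of LC-MS/GC-MS Metabolomics Peak Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quality assessment, filtering, imputation and normalization of
    metabolomics peak tables, including QC-sample-based signal-drift correction
    (robust smoothing splines and support vector regression) and empirical-Bayes
    batch adjustment; univariate statistics with false discovery control, fold
    change and ROC; PCA, PLS-DA and OPLS-DA with VIP, cross-validated Q2 and
    permutation testing; power and sample-size curves; correlation and
    differential-correlation networks with community detection; adduct-aware
    ppm-tolerance metabolite identification against local compound databases;
    recursive-feature-elimination biomarker selection; a seeded synthetic-data
    generator with known ground truth; and self-contained HTML reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    limma,
    mixOmics,
    optparse,
    pROC,
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
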