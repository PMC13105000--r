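Package: karyotme
Title: Linking Somatic Copy-Number Alterations to the Tumor Immune
    Microenvironment and Immunotherapy Survival
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating arm-, cytoband-, and gene-level somatic
    copy-number alterations (SCNAs) to immune phenotypes of the tumor
    microenvironment. Implements a rank-sum cytotoxic Immune Score over
    seven cytotoxic-lymphocyte genes, purity/ploidy adjustment and
    gain/loss calling of log2 copy-number profiles, an aneuploidy-score-
    adjusted, direction-stratified logistic and linear regression engine
    with Benjamini-Hochberg correction and signed association landscapes,
    a gene-level caller for tumor immune suppressor genes (TiSG) and
    immune oncogenes (iOG) from DNA:IS, RNA:IS and DNA:RNA correlations
    with LASSO feature selection and a random-forest classifier interface,
    arm-level Cox survival landscapes with Kaplan-Meier stratification and
    an expression-based chromosome-1q inference score, and a seeded
    synthetic-cohort generator with planted effects for end-to-end
    validation without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    glmnet,
    randomForest,
    pROC
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
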