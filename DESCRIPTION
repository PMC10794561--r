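Package: metacvd
Title: Meta Polygenic Risk Scores for Cardiovascular Disease in Type 2 Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds and evaluates a variance-normalized meta polygenic risk
    score (meta-PRS) for cardiovascular disease (CVD) among type 2 diabetes
    patients, combining standardized subtype scores for coronary artery
    disease, ischemic stroke and heart failure via Cox regression
    coefficients and their correlation matrix. Includes a synthetic study
    generator emulating biobank genotype dosages, GWAS summary statistics
    with correlated per-variant effects, coded hospital-episode records and
    clinical covariates; phenotype ascertainment from ICD9/ICD10/OPCS4
    codes; allele-harmonized polygenic scoring with a reference
    clumping-and-thresholding weight generator; proportional-hazards,
    ROC/AUC, Kaplan-Meier and quantile-incidence kernels; and five-fold
    cross-validated evaluation with onset-age and sex stratified reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
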