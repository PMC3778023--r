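Package: riskcat
Title: Simulation-Based Risk Categorisation for Gene-Environment Disease
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds disease risk prediction models from published summary
    statistics (allelic odds ratios, allele frequencies, environmental
    exposure odds ratios) by combining risk factors multiplicatively and
    classifying risk profiles into reduced, average, elevated and high risk
    categories through confidence-interval comparison against a simulated
    general-population risk distribution. Supports multi-allelic HLA loci
    typed at mixed (two- and four-digit) resolution, individual-level
    scoring with eligibility rules, lifetime-risk conversion, ROC/AUC
    discrimination with DeLong variance and paired tests, Kaplan-Meier
    age-of-onset stratification with log-rank tests, and a synthetic
    case-control cohort generator for end-to-end validation. Ships the
    rheumatoid-arthritis risk-factor tables (HLA-DRB1 alleles, 34
    susceptibility SNPs, male ever-smoking) used throughout the examples.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    survival,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
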