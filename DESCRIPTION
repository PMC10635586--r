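Package: rpqcluster
Title: Symptom-Cluster Analysis of the Rivermead Post-Concussion Questionnaire
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Corrected scoring of the 16-item Rivermead Post-Concussion
    Symptoms Questionnaire (RPQ-16), Spearman-correlation-profile
    agglomerative hierarchical clustering of symptoms with an
    earliest-singleton-free cluster-formation rule, participant assignment to
    symptom clusters under mean/any/all severity criteria, and association
    analyses between symptom-cluster membership and self-reported functional
    impairments with Bonferroni families, odds ratios and sensitivity
    analyses. Includes a Gaussian-copula synthetic cohort generator with
    planted ordinal correlation blocks and logistic cluster-to-impairment
    effects so the full pipeline can be exercised and calibrated without
    access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    ape,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
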