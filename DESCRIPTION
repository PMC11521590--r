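Package: somrisk
Title: Mixed-Type Clinical Cohort Clustering and Pregnancy Risk Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters mixed categorical/numerical clinical cohorts with a
    batch-trained self-organizing map (SOM) and a two-level minicluster merge,
    and profiles the resulting patient clusters into high/moderate/low risk
    tiers. Categorical labels are converted to numeric scores through
    co-occurrence (Jaccard) similarity with a set of binary base
    manifestations, so that laboratory labels, delivery types and numeric
    attributes can enter a single feature matrix. Includes a synthetic cohort
    generator that emulates a 119-patient pregnancy cohort of systemic lupus
    erythematosus (SLE) patients with five latent clusters, for end-to-end
    testing of the pipeline without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
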