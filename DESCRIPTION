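Package: ricearoma
Title: Flavor Metabolomics of Rice Aroma Types
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: An analysis pipeline for classifying commercial rice by aroma
    type and identifying the volatile compounds behind the differences.
    Combines quantitative descriptive analysis (QDA) sensory panels with
    untargeted GC-MS and GC-IMS volatile profiling: Ward clustering of
    aroma profiles with within-cluster sum of squares (WCSS) elbow
    selection, retention-index identification and internal-standard
    semi-quantification, relative odor activity values (ROAV) for key
    aroma compound ranking, differential screening by one-way ANOVA and
    pairwise Student t tests gated on OPLS-DA variable importance (VIP),
    and GC-IMS fingerprint and monomer/dimer analysis. Includes a
    synthetic-data generator reproducing the study design so every stage
    is testable from the published summary tables alone.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
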