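Package: crisiswell
Title: Wearable and Self-Report Wellbeing Analysis Around an Acute Crisis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing smartwatch, smartphone and daily-questionnaire
    wellbeing indicators collected around an acute population-level crisis such
    as an armed conflict. Provides a synthetic cohort generator emulating the
    study design (four contiguous calendar periods, a work/free-day weekly
    rhythm, exposure-group shifts sized in Cohen's d, questionnaire missingness
    and siren-triggered heart-rate impulses), ingestion and cleaning of the
    per-participant CSV tables, GPS-based residence inference and three-tier
    distance-to-conflict exposure classification, 5/7-2/7 work/free weighted
    period aggregation with per-test inclusion filters, a windowed siren
    heart-rate response statistic, a split-plot mixed ANOVA with Bonferroni
    post hoc tests and paired Cohen's d, and an additive Type-III subgroup
    ANOVA on war-minus-baseline changes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
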