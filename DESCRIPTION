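Package: dxensemble
Title: Plurality-Preserving Orchestration of Diagnostic Model Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Orchestrates heterogeneous diagnostic models over clinical
    cases while preserving, rather than collapsing, their disagreement.
    Provides a model provenance registry, structured ingestion of ranked
    differential diagnoses with ICD-10 code validation and hedging-lexicon
    scoring, synonym clustering of candidate diagnoses, agreement-rate
    stratification into primary/alternative/minority strata, bias
    attribution by provenance group (geography, cost tier, demographic
    salience), plurality-preserving clinical reports with progressive
    disclosure, a failover synthesizer chain, and a fully seeded synthetic
    biased-ensemble simulator so that every pipeline stage is verifiable
    offline without commercial model APIs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
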