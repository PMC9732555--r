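Package: pdnet
Title: Bayesian Diagnostic Network for Dramatic and Emotional Personality Disorders
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and queries a three-layer augmented BN2O Bayesian network
    for the five cluster-B (dramatic and emotional) personality disorders:
    antisocial, borderline, narcissistic, histrionic and passive-aggressive.
    Ships the expert-elicited knowledge base (influence probabilities,
    population baselines, psychological-distress links and prevalences) as
    plain-text parameter tables; generates conditional probability tables via
    leaky noisy-OR, leaky noisy-MAX and an additive evidence-weighting model
    for graded traits; performs exact posterior inference by disorder
    configuration enumeration; derives likelihood-ratio screening and
    confirmatory symptom panels; provides strength-of-influence and
    finding-impact sensitivity analyses, Delphi consensus aggregation for
    parameter elicitation, XMLBIF interchange, a seeded synthetic fixture
    generator, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
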