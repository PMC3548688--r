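Package: fuzzydx
Title: Automatic Generation of Fuzzy Rule-Based Diagnostic Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds fuzzy rule-based diagnostic decision support systems from
    tabular clinical data in six stages: weighted-DNF crisp rules are extracted
    from a gain-ratio decision tree, ranked and selected (at least one rule per
    class), reduced into fuzzifiable form by merging comparable numeric
    predicates, translated into linguistic variables and a weighted fuzzy rule
    base, assembled into a configurable fuzzy inference system (singleton or
    Mamdani reasoning, min/product t-norms, center-of-gravity defuzzification),
    and tuned by adaptive-step cyclic coordinate descent minimising mean
    squared error. Includes stratified cross-validation, synthetic data
    generation from known rule bases, and IEC 61131-7 Fuzzy Control Language
    import/export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
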