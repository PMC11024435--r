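Package: extractprio
Title: Bioactivity- and Novelty-Driven Prioritization of Natural Extracts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for triaging large natural-extract collections screened
    against the Wnt/beta-catenin pathway with a dual-luciferase reporter
    assay. Provides four-parameter-logistic dose-response fitting with IC50
    tiering and a Renilla-based cytotoxicity rule, MEMO-style MS2 spectral
    fingerprints (binned fragment peaks and neutral losses) with ensemble
    outlier detection, four per-extract structural-novelty component scores
    (Feature, Literature, Class, Similarity) combined into a Priority Score,
    and the sequential selection cascade that reduces a screened collection
    to a ranked shortlist. Includes molecular-formula mass calculus
    (monoisotopic masses, adduct m/z, ppm errors, constrained formula
    assignment) and a synthetic-collection generator with planted ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
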