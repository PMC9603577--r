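Package: cdkl5sat
Title: Saturation In Silico Pathogenicity Analysis of the CDKL5 Catalytic Domain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comprehensive in-silico saturation analysis of a
    protein catalytic domain, built around the CDKL5 serine/threonine kinase
    (residues 1-300). Enumerates all 19 single amino-acid substitutions per
    position, parses native report formats of the PolyPhen-2 (HumDiv/HumVar),
    PROVEAN and SIFT predictors, classifies raw scores against published
    thresholds, combines tools into consensus calls and P3/P2/B2/B3 tiers,
    benchmarks every tool combination against a labelled reference set with
    accuracy, sensitivity, specificity and the Matthews correlation
    coefficient, summarises cross-species conservation over functional
    regions, tests pathogenic-call enrichment in critical versus non-critical
    regions, and generates seeded synthetic score tables and reference sets
    so the whole pipeline runs without prediction-server access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
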