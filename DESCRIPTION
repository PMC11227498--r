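Package: ihcsub
Title: Immunohistochemistry-Based Expression Subtyping of Pancreatic
    Ductal Adenocarcinoma
Version: 0.1.0
Authors@R:
    person("Ihcsub", "Developers", email = "ihcsub@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying pancreatic ductal adenocarcinoma
    (PDAC) into Classical, Transitional and Basal-like expression
    patterns from a four-marker immunohistochemistry panel (CK5/6, p63,
    GATA6, HNF4a) scored on the Allred scale. Provides Allred scoring
    and the four-grade collapse, Ward hierarchical clustering of the
    grade matrix with deterministic pattern labeling, the explicit
    decision rules for pattern prediction, exact association tests
    (Fisher and Freeman-Halton with enumeration and Monte Carlo
    fallback), Kaplan-Meier / log-rank / Gehan-Wilcoxon / Cox survival
    analysis, bulk-expression signature scoring including a custom
    five-gene basal-vs-classical score, and seeded synthetic cohort and
    expression generators so the entire pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
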