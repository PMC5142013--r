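Package: panffl
Title: Dysregulated TF-miRNA Feed-Forward Loops Across Tumor Types
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies transcription-factor (TF) and microRNA (miRNA)
    feed-forward loops (FFLs) that are dysregulated between matched tumor
    and normal samples. Builds a typed background regulatory network from
    curated regulation tables, enumerates and classifies three-node FFLs
    (TF-FFL, miRNA-FFL, FB-FFL), scores each loop per tumor type by
    combining node differential expression (inverse-normal transform of
    P-values) with edge differential co-expression (standardized Fisher-z
    difference of Spearman correlations), assigns permutation-based
    empirical P-values against random molecule triples, and aggregates
    results across tumor types into pan-cancer FFLs with enrichment and
    topology statistics. Includes a negative-binomial synthetic-data
    generator with Gaussian-copula rank correlation so the whole pipeline
    is testable with known planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
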