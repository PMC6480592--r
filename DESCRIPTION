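Package: ontosql
Title: Ontology-Aware Semantic Queries over SQL Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Embeds free-text, ontology-aware expressions of the form
    [prefix][relation][{modifier}][:depth][[query]](table.column, ...) in
    otherwise standard SQL, resolves them against an in-process terminology
    (isA/partOf/labelled context edges), and rewrites the query to plain SQL
    IN-clauses over pre-built annotation tables.  Includes the annotation
    pipeline that maps free clinical text to concepts (abbreviation
    expansion, spell correction, compound splitting, greedy longest match)
    and materializes direct matches plus all isA ancestors with their
    semantic distance; a synthetic clinical-corpus generator with ground
    truth; and evaluation statistics (sensitivity, specificity, PPV,
    prevalence, F-score with exact binomial confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    DBI,
    RSQLite,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
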