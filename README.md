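# ontosql — ontology-aware semantic queries over SQL databases

`ontosql` lets you query free-text columns of a relational database
*semantically*, in otherwise standard SQL.  It is aimed at clinical
informatics settings — research databases of diagnoses, epicrises and
course-of-death narratives — where the interesting information sits in
short, noisy free text full of abbreviations, misspellings and (in
German) concatenated compound nouns, and where a terminology (isA
taxonomy, partOf relations, labelled context relations such as
*indication* or *side effect*) describes the domain.

The core mechanism has two halves:

1. **Annotation tables.** For every searchable column `T.C`, a side table
   `_T_C` is built once: each row's text is mapped to terminology
   concepts (abbreviation expansion, spell correction, compound
   splitting, greedy longest match) and stored together with **all isA
   ancestors** of each matched concept, at their minimal semantic
   distance `Level` (direct matches have `Level = 0`).  Rows link back to
   the source table by its primary key; source tables are never touched.
2. **Query rewriting.** Semantic expressions of the form

   ```
   [prefix][relation][{modifier}][:depth][[query]](table.column, ...)
   ```

   embedded in a SQL query are resolved against the terminology and
   replaced in place by plain `IN`-clauses over the annotation tables:

   ```
   SELECT * FROM table_name WHERE [cephalea](Description)
     -->  SELECT * FROM table_name WHERE ID IN (...)
   ```

   Because ancestors are materialized, subsumption is a membership test:
   querying a concept matches every record annotated with it *or any
   descendant*.  `NOT`, `AND`, `OR` and parentheses work as in any SQL.

Relations: `isA` (default; subsumption), `partOf` (transitive closure of
parts, e.g. the agents of a drug product), and `context{modifier}` /
`hasContext{modifier}` with an optional `:depth` that inherits context
attributes down the taxonomy (`depth` generations, the query concept
being generation 1; default 1 = no inheritance).  A `+` prefix includes
the query concepts themselves.

## Worked example

```r
library(ontosql); library(DBI)

ont <- generate_demo_ontology()            # small wired demo terminology
con <- dbConnect(RSQLite::SQLite(), ":memory:")
build_demo_db(con, ont)                    # tables + annotation tables

annotate_text("cluster headache for two weeks", ont)
#>   concept_id        concept_label start end             text match_kind score
#> 1    D0009F4 Bing-Horton syndrome     0  16 cluster headache    synonym  0.95
#> 2    Z000002                  two    21  24              two      exact  1.00
#> 3    GA000F8                 week    25  30            weeks    synonym  0.95
```

"cluster headache" is a synonym of the Bing-Horton-syndrome concept,
which sits four isA edges below "cephalea"; the annotation table
therefore stores that ancestor at `Level = 4`, and a subsumption query
for the ancestor finds the record:

```r
res <- execute_osql(
  "SELECT DiagnosisId, Diagnosis FROM diagnoses WHERE [cephalea](Diagnosis)",
  con, ont)
res$rows
#>   DiagnosisId                      Diagnosis
#> 1           1 cluster headache for two weeks
res$sql
#> SELECT DiagnosisId, Diagnosis FROM diagnoses WHERE DiagnosisId IN (1)
```

A two-expression query combining partOf and a context relation (the
rewrite report shows which concepts were actually used):

```r
rewrite_osql(
  "select * from tableMed, tableDiag where tableMed.CID = tableDiag.CID and
   +partOf[Prandin](tableMed.Drug) and
   hasContext{side effect}[repaglinide](tableDiag.Diag)", con, ont)
#> select * from tableMed, tableDiag where tableMed.CID = tableDiag.CID and
#>  tableMed.MedId IN (1, 2) and tableDiag.DiagId IN (1, 2)
#> -- +partOf[Prandin](tableMed.Drug) => partOf, 2 concept(s) [Prandin]
#> -- hasContext{side effect}[repaglinide](tableDiag.Diag) => context{side effect}, 1 concept(s) [repaglinide]
```

The side-effect query returns both the record that literally says
"hypoglycemia" and the one that says "hyperinsulinism", because
hyperinsulinism isA hypoglycemia and the ancestor row is materialized.

Evaluation on a synthetic noisy corpus (500 records, per-token
misspelling rate 0.1, abbreviation substitution 0.2, seed 42) against the
generator's ground truth:

```r
corpus <- generate_corpus(ont, 500, noise_config())
build_annotation_table(corpus$con, corpus$table, corpus$column, ont)
ann <- dbGetQuery(corpus$con,
  "SELECT RecordId AS record_id, ConceptID AS concept_id
     FROM _records_Diagnosis WHERE Level = 0")
evaluate_annotation(ann, corpus$truth, universe = corpus_concepts(ont))
#> TP 967  FP 2  TN 10499  FN 32
#> Sensitivity               96.80% (CI 95%: 95.51-97.80%)
#> Specificity               99.98% (CI 95%: 99.93-100.00%)
#> Positive predictive value 99.79% (CI 95%: 99.26-99.97%)
#> Prevalence                8.69% (CI 95%: 8.18-9.22%)
#> F score                   0.98
```

Confidence intervals are exact (Clopper–Pearson) binomial intervals.

## Command line

```sh
Rscript inst/cli/osql.R init-demo --dir demo
Rscript inst/cli/osql.R query --db demo/demo.db --ontology demo/ontology.jsonl \
    --explain "SELECT DiagnosisId FROM diagnoses WHERE [chd](Diagnosis)"
Rscript inst/cli/osql.R eval --n 500 --seed 42 --json
```

Exit codes: 0 ok, 1 semantic-resolution error (e.g. query text that maps
to no concept), 2 environment/SQL error.

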