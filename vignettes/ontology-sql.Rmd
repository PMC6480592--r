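---
title: "Semantic queries over free-text columns: the ontosql model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic queries over free-text columns: the ontosql model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontosql)
library(DBI)
```

## The problem

Clinical databases routinely keep their most informative content in
free-text columns: diagnoses, course-of-death narratives, epicrises.
Querying such columns with plain SQL means `LIKE` patterns that know
nothing about terminology — a search for "hypoglycemia" misses the record
that says "hyperinsulinism", a search for "coronary heart disease" misses
the note that says "chd", and nothing copes with the abbreviations,
misspellings and (in German) concatenated compound nouns that clinical
shorthand produces.

`ontosql` addresses this in two stages:

1. **Annotation.** Every free-text column that should be semantically
   searchable is annotated once, offline: each row's text is mapped to
   concepts of a terminology, and the matches — together with *all their
   isA ancestors* — are stored in a side table linked to the source row
   by its primary key.
2. **Query rewriting.** At query time, a semantic expression embedded in
   otherwise standard SQL,

   ```
   [prefix][relation][{modifier}][:depth][[query]](table.column, ...)
   ```

   is resolved against the same terminology and replaced by a plain SQL
   `IN`-clause over the annotation table.  The engine then runs ordinary
   SQL; `NOT`, `AND`, `OR` and parentheses keep their usual meaning.

Because ancestors are materialized at annotation time, *subsumption
becomes a membership test*: a query for "cephalea" matches every record
annotated with any kind of headache, without recursive SQL.

## The data model

An **ontology** is a set of concepts (identifier, preferred label,
synonyms, abbreviations) plus typed edges:

* `isA` — the taxonomy; must be acyclic, validated at load time;
* `partOf` — mereology (the agents contained in a drug product); cycles
  are tolerated and closures terminate by visited set;
* `context` — a generic relation specialized by a free-text label such as
  `"indication"` or `"side effect"`, which keeps the query syntax
  independent of any particular ontology's relation inventory.

The **annotation table** for source table `T`, column `C` is named
`_T_C` and has four columns: the source key, `ConceptID`, `ConceptLabel`,
and `Level` — the *semantic distance*, i.e. the minimal number of isA
edges from a directly matched concept of that record (direct matches have
`Level = 0`).  Each `(key, ConceptID)` pair is stored once at its global
minimal level; membership queries only need existence, and uniqueness
keeps the tables small.  Indexes on `ConceptID` and the key column make
the rewritten queries index scans.

```{r}
ont <- generate_demo_ontology()
con <- dbConnect(RSQLite::SQLite(), ":memory:")
build_demo_db(con, ont)
dbGetQuery(con, "SELECT * FROM _diagnoses_Diagnosis WHERE DiagnosisId = 1")
```

The "cluster headache for two weeks" record carries three direct concepts
and the full headache taxonomy above them, up to "cephalea" at distance 4.

## Expression semantics

The free-text `query` part is put through the same annotator as stored
text, so it tolerates abbreviations and typos.  The resulting query
concepts `Q` are then expanded by the relation:

* `isA` (the default): the concept set is `Q` itself — subsumption is
  realized by the materialized ancestors, so records annotated with any
  descendant are matched.  When `:depth` is combined with `isA`, it is
  interpreted as bounding the subsumption generations (`Level <= depth -
  1`) and flagged in the rewrite report.
* `partOf`: the transitive closure of parts of each query concept.
* `context{modifier}` / `hasContext{modifier}`: context attributes are
  inherited *down* the taxonomy up to `depth` generations, with the query
  concept counting as generation 1 and a default depth of 1 (no
  inheritance, making inheritance strictly opt-in).  The result is the
  set of context-edge targets over those generations.
* A `+` prefix adds `Q` itself to the result set.

```{r}
execute_osql(
  "SELECT NoteId, Drug FROM fig3 WHERE hasContext{indication}:2[Analgesic](Drug)",
  con, ont)$rows
```

At depth 1 this query matches nothing (Analgesic itself has no indication
edges); at depth 2 the indications of its child Ibuprofen — Pain and
Fever — are inherited.

Query text that resolves to no concept raises an error rather than
returning an empty result, and every rewrite carries a report of the
concepts actually used: a silently misread abbreviation would otherwise
produce undetectably wrong result sets.

## The annotator

The reference pipeline approximates a full NLP terminology server with
deterministic, testable steps:

1. **Normalization** — lower-casing, umlaut/eszett folding (ä→ae, ß→ss),
   diacritic stripping; punctuation is split off, except periods inside
   abbreviation-shaped tokens (`"Schw.brtg"` stays one token).  Offsets
   always reference the original text.
2. **Abbreviation expansion** from a TSV dictionary (multiple expansions
   per abbreviation allowed); ontology-declared abbreviations are also in
   the lexical index directly.
3. **Recovery of out-of-vocabulary tokens** by suffix stripping
   (configurable rules, default `s/es/en/e`), spell correction, and
   compound splitting into two or more lexicon words (minimum subword
   length 4, fuzzy parts allowed at their edit cost).
4. **Greedy longest match**: token windows are looked up in the index of
   normalized labels/synonyms/abbreviations, longest span first;
   stop-words are skippable inside a window but never emit concepts;
   ties break by higher score, then smaller concept id.  Scores are 1 for
   exact label matches and strictly below 1 otherwise (synonym 0.95,
   abbreviation 0.9, spell correction 0.85/0.70 by distance,
   compound split 0.85).

The spell-correction threshold is banded by token length — 0 edits for
tokens of up to 4 characters, 1 for 5–8, 2 for 9 or more — because short
clinical tokens ("pain", "icd") are one edit away from too many other
short words.  Distances are plain Levenshtein (`utils::adist`), under
which a transposition costs 2; a transposed 5–8-character word is
therefore *not* recovered.  This is a deliberate, known sensitivity cost
(see below) rather than a tuning target.

The disambiguation of the original system (collocation-based, proprietary)
is replaced by the deterministic tie-break above; this is sufficient for
all worked examples and makes every result reproducible.

## The synthetic corpus and what it does (not) show

`generate_corpus()` emulates short clinical narratives: each record embeds
1–3 concept labels (preferred label or synonym) in filler text and then
perturbs the text with three seeded noise channels:

* **misspellings** — each whitespace token receives, with probability
  `misspell` (default 0.1), one random edit drawn uniformly from
  substitute/transpose/delete/insert;
* **abbreviation substitution** — an embedded concept that has an
  abbreviation is written as the abbreviation with probability `abbrev`
  (default 0.2);
* **compound concatenation** — a multi-word label has its adjacent
  alphabetic words joined with probability `compound` (default 0.1; the
  rate mirrors how often shortened compounds appeared relative to other
  distortions in historical clinical text, and was fixed once as part of
  the study conditions).

The defaults (misspell 0.1, abbrev 0.2, compound 0.1, seed 42) are the
package's study conditions.  The ground truth records exactly the
embedded concepts, the clean text and the realized edit count, so tests
can recount the noise independently.  Filler vocabulary is screened at
generation time to sit at Levenshtein distance ≥ 4 from every lexicon
word, so spell correction cannot cross-map filler tokens into concepts —
specificity losses in the evaluation are therefore attributable to the
annotator, not to generator artifacts.

What passing these tests shows: the pipeline recovers embedded concepts
through realistic *surface* noise and the full query stack returns
exactly the records a per-row brute-force evaluator selects.  What it
does not show: performance on real clinical narratives, whose noise is
not independent per token, whose vocabulary is orders of magnitude
larger, and whose ambiguity (competing senses of one token) the
generator does not model.

## Evaluation statistics

`eval_result()` computes sensitivity, specificity, PPV, prevalence and
F-score (`2·PPV·sens/(PPV+sens)`) from confusion counts, each rate with
its exact Clopper–Pearson 95% binomial interval (`stats::binom.test`);
the exact method is used because it is what the clinical-statistics
packages this mirrors report for sensitivity/specificity tables.
`evaluate_annotation()` scores per-(record × concept) pairs over the full
eligible-concept grid; `evaluate_flags()` scores record-level binary
labels (flags default to "embeds any descendant of an isA root").

## Numerical and design choices

* **Depth convention**: depth *d* inspects *d* generations with the query
  concept as generation 1 — chosen so that context inheritance is off by
  default and indications of a direct child appear exactly at depth 2.
* **Empty key sets** rewrite to `key IN (SELECT NULL WHERE 1=0)` rather
  than `IN (NULL)`: under SQL three-valued logic the latter would make
  `NOT <atom>` select zero rows instead of the complement.
* **Key enumeration**: literal `IN`-lists up to 10,000 keys (a simple
  enumeration the engine turns into an index scan), switching to a
  temporary-table join above that.
* **Bare target columns** (`(Drug)` instead of `(tableMed.Drug)`) resolve
  against the query's FROM clause only when it names exactly one table;
  anything else is an error rather than a guess.
* **Context labels** match case-insensitively with collapsed whitespace,
  since modifiers are free text.
* **`context` without a modifier** is rejected at parse time — there is
  no meaningful edge-label to match.
* Problem sizes in the test suite (200–500 synthetic records, 100 random
  DAGs of up to 100 nodes, 50 random queries) were chosen as the smallest
  sizes at which the statistical properties stabilize across seeds.

## Known limitations

* No nested semantic expressions (an expression inside another's query
  text); concatenated expressions cover the examined use cases.
* Atomic concepts only: no post-coordination of composed meanings.
* No negation detection or section segmentation in the annotator; a
  narrative "no fever" is annotated with the fever concept.
* Only isA ancestors are materialized in annotation tables; partOf
  closures are computed at query time on the concept side.
* The OBO reader covers the `[Term]`/`id`/`name`/`synonym`/`is_a`/
  `relationship: part_of` subset only.

```{r, include = FALSE}
dbDisconnect(con)
```
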