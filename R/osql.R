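## O-SQL expression grammar:
##   [prefix][relation][{modifier}][:depth][[query]](table.column, ...)
## prefix "+" additionally includes the query concepts themselves; relation
## defaults to isA; the generic "context"/"hasContext" relation takes a
## free-text {modifier}; ":depth" bounds isA generations (the query concept
## counting as generation 1).

OSQL_PATTERN <- paste0(
  "(\\+)?",                                             # 1 prefix
  "((?:(?<![A-Za-z0-9_])(?i:isA|partOf|hasContext|context))(?![A-Za-z0-9_]))?", # 2 relation
  "(\\s*\\{[^{}]*\\})?",                                # 3 modifier
  "(\\s*:[0-9]+)?",                                     # 4 depth
  "\\s*\\[([^][]*)\\]",                                 # 5 query
  "\\s*\\(([^()]*)\\)"                                  # 6 targets
)

## Blank out single-quoted SQL string literals ('' escapes a quote),
## preserving string length so offsets stay valid.
mask_literals <- function(sql) {
  chars <- strsplit(sql, "", fixed = TRUE)[[1L]]
  inq <- FALSE
  for (i in seq_along(chars)) {
    if (chars[[i]] == "'") { inq <- !inq; chars[[i]] <- " "; next }
    if (inq) chars[[i]] <- " "
  }
  paste(chars, collapse = "")
}

#' Locate O-SQL expressions in a SQL string
#'
#' Finds every embedded O-SQL expression with its exact character span.
#' Text inside single-quoted SQL string literals is never matched.  A
#' square bracket outside any literal that does not belong to a complete
#' expression raises a syntax error naming its position.
#'
#' @param sql SQL text possibly containing O-SQL expressions.
#' @return Data frame with columns `start`, `end` (1-based inclusive
#'   character span) and `raw` (the expression text).
#' @export
extract_expressions <- function(sql) {
  if (!is_string(sql) || !nzchar(sql))
    osql_parse_error("sql text must be a non-empty string")
  masked <- mask_literals(sql)
  m <- gregexpr(OSQL_PATTERN, masked, perl = TRUE)[[1L]]
  if (m[1L] == -1L) {
    spans <- data.frame(start = integer(), end = integer(), raw = character(),
                        stringsAsFactors = FALSE)
  } else {
    starts <- as.integer(m)
    ends <- starts + attr(m, "match.length") - 1L
    raw <- substring(sql, starts, ends)
    # leading whitespace swallowed by the pattern is not part of the span
    lead <- nchar(raw) - nchar(sub("^\\s+", "", raw))
    starts <- starts + lead
    raw <- substring(sql, starts, ends)
    spans <- data.frame(start = starts, end = ends, raw = raw,
                        stringsAsFactors = FALSE)
  }
  # any bracket left outside matched spans is unbalanced / stray
  covered <- rep(FALSE, nchar(sql))
  for (i in seq_len(nrow(spans))) covered[spans$start[i]:spans$end[i]] <- TRUE
  chars <- strsplit(masked, "", fixed = TRUE)[[1L]]
  stray <- which((chars == "[" | chars == "]") & !covered)
  if (length(stray))
    osql_parse_error(sprintf(
      "unbalanced bracket '%s' at position %d", chars[[stray[1L]]], stray[1L]))
  # a word glued onto the front of an expression is an unknown relation keyword
  for (i in seq_len(nrow(spans))) {
    s <- spans$start[[i]]
    if (s > 1L && grepl("^[\\[+]", spans$raw[[i]]) &&
        grepl("[A-Za-z0-9_]", substr(masked, s - 1L, s - 1L))) {
      word <- sub(".*?([A-Za-z0-9_]+)$", "\\1", substr(masked, 1L, s - 1L))
      osql_parse_error(sprintf(
        "unknown relation keyword '%s' before expression at position %d",
        word, s))
    }
  }
  spans
}

#' Parse one O-SQL expression
#'
#' @param raw Expression text as located by [extract_expressions()].
#' @return List of class `osql_expression` with fields `prefix` (logical),
#'   `relation` (`"isA"`, `"partOf"` or `"context"`), `modifier`
#'   (string or `NA`), `depth` (integer or `NA`), `query` (free text) and
#'   `targets` (data frame with columns `table` — `NA` when omitted — and
#'   `column`).
#' @export
parse_expression <- function(raw) {
  m <- regexec(paste0("^\\s*", OSQL_PATTERN, "\\s*$"), raw, perl = TRUE)[[1L]]
  if (m[1L] == -1L)
    osql_parse_error(sprintf("not a valid O-SQL expression: %s", raw))
  g <- regmatches(raw, list(m))[[1L]]
  prefix <- nzchar(g[[2L]])
  relation_raw <- trimws(g[[3L]])
  relation <- if (!nzchar(relation_raw)) "isA" else
    c(isa = "isA", partof = "partOf", context = "context",
      hascontext = "context")[[tolower(relation_raw)]]
  modifier <- if (nzchar(g[[4L]]))
    trimws2(sub("^\\s*\\{(.*)\\}$", "\\1", g[[4L]])) else NA_character_
  if (!is.na(modifier) && !nzchar(modifier))
    osql_parse_error(sprintf("empty context modifier in: %s", raw))
  depth <- if (nzchar(g[[5L]]))
    as.integer(sub("^\\s*:", "", g[[5L]])) else NA_integer_
  if (!is.na(depth) && depth < 1L)
    osql_parse_error(sprintf("depth must be a positive integer in: %s", raw))
  if (!is.na(modifier) && relation != "context")
    osql_parse_error(sprintf(
      "modifier {%s} requires the context relation in: %s", modifier, raw))
  if (relation == "context" && is.na(modifier))
    osql_parse_error(sprintf(
      "context relation requires a {modifier} in: %s", raw))
  query <- trimws(g[[6L]])
  if (!nzchar(query))
    osql_parse_error(sprintf("empty query text in: %s", raw))
  tgt <- trimws(strsplit(g[[7L]], ",", fixed = TRUE)[[1L]])
  tgt <- tgt[nzchar(tgt)]
  if (!length(tgt))
    osql_parse_error(sprintf("empty target list in: %s", raw))
  parts <- strsplit(tgt, ".", fixed = TRUE)
  if (any(lengths(parts) > 2L))
    osql_parse_error(sprintf("malformed target '%s' in: %s",
                             tgt[lengths(parts) > 2L][1L], raw))
  targets <- data.frame(
    table = vapply(parts, function(p) if (length(p) == 2L) p[[1L]] else NA_character_,
                   character(1)),
    column = vapply(parts, function(p) p[[length(p)]], character(1)),
    stringsAsFactors = FALSE)
  structure(
    list(prefix = prefix, relation = relation, modifier = modifier,
         depth = depth, query = query, targets = targets, raw = raw),
    class = "osql_expression")
}

#' Resolve an O-SQL expression to a concept set
#'
#' The free-text query is annotated against the ontology (so it enjoys
#' the same abbreviation/spelling tolerance as stored text); the
#' resulting query concepts are then expanded by the expression's
#' relation:
#'
#' * `isA` — the query concepts themselves (annotation tables already
#'   materialize all isA ancestors, so a membership lookup realizes
#'   subsumption);
#' * `partOf` — the transitive [part_of_closure()] of each query concept;
#' * `context` — [context_targets()] of the [descendants()] of each query
#'   concept down to `depth` generations (default 1: no inheritance),
#'   for the expression's modifier label.
#'
#' A `+` prefix additionally includes the query concepts themselves.
#' Query text that maps to no concept is a hard error, so that a
#' misinterpreted abbreviation cannot silently return an empty result.
#'
#' @param expr An [parse_expression()] result.
#' @param ontology An [ontology()].
#' @param config An [annotator_config()].
#' @return List with `set` (character vector of concept ids) and
#'   `query_concepts` (data frame `concept_id`, `concept_label`).
#' @export
resolve_concept_set <- function(expr, ontology, config = annotator_config()) {
  ann <- annotate_text(expr$query, ontology, config)
  if (!nrow(ann))
    osql_semantic_error(sprintf(
      "query text '%s' could not be resolved to any concept", expr$query))
  q <- unique(ann$concept_id)
  set <- switch(expr$relation,
    isA = q,
    partOf = unique(unlist(lapply(q, part_of_closure, ontology = ontology))),
    context = {
      depth <- if (is.na(expr$depth)) 1L else expr$depth
      src <- unique(unlist(lapply(q, descendants, ontology = ontology,
                                  max_generations = depth)))
      context_targets(ontology, src, expr$modifier)
    })
  if (expr$prefix) set <- union(set, q)
  list(set = sort(unique(set %||% character())),
       query_concepts = data.frame(
         concept_id = q, concept_label = concept_label(ontology, q),
         stringsAsFactors = FALSE))
}

.osql_state <- new.env(parent = emptyenv())
.osql_state$tmp_id <- 0L
next_tmp_id <- function() {
  .osql_state$tmp_id <- .osql_state$tmp_id + 1L
  .osql_state$tmp_id
}

## SQL literal for a vector of keys (numeric unquoted, text quoted).
sql_keys <- function(con, keys) {
  if (is.numeric(keys)) as.character(keys)
  else vapply(keys, function(k)
    as.character(DBI::dbQuoteString(con, as.character(k))), character(1))
}

#' Build the standard-SQL subclause for one expression
#'
#' For each target `(table, column)` the annotation table is queried for
#' the record keys whose `ConceptID` lies in `concept_set`; the clause is
#' `<key> IN (k1, ...)` per target, multiple targets joined with `OR` and
#' parenthesized.  An empty key set yields `<key> IN (SELECT NULL WHERE
#' 1=0)`, which matches no rows while keeping two-valued logic under
#' `NOT`.  Beyond `max_inline_keys` keys the enumeration switches to a
#' temporary-table join.
#'
#' @param con DBI connection with annotation tables built.
#' @param expr An `osql_expression`.
#' @param concept_set Character vector of concept ids (from
#'   [resolve_concept_set()]).
#' @param default_table Table used for targets written without an
#'   explicit table name (`NA` when ambiguous).
#' @param max_inline_keys Largest literal IN-list emitted (default 10000).
#' @return List with `clause` (SQL boolean expression) and `targets`
#'   (data frame `table`, `column`, `n_keys`).
#' @export
build_subclause <- function(con, expr, concept_set, default_table = NA,
                            max_inline_keys = 10000L) {
  pieces <- character()
  counts <- integer()
  tables <- character()
  level_cap <- if (expr$relation == "isA" && !is.na(expr$depth))
    expr$depth - 1L else NA_integer_
  for (i in seq_len(nrow(expr$targets))) {
    tbl <- expr$targets$table[[i]]
    qualified <- !is.na(tbl)
    if (!qualified) {
      if (is.na(default_table))
        osql_db_error(sprintf(
          "target column '%s' has no table name and the query's FROM clause is ambiguous",
          expr$targets$column[[i]]))
      tbl <- default_table
    }
    col <- expr$targets$column[[i]]
    ann <- annotation_table_name(tbl, col)
    if (!DBI::dbExistsTable(con, ann))
      osql_db_error(sprintf(
        "annotation table '%s' for target %s.%s does not exist; build it first",
        ann, tbl, col))
    key <- setdiff(DBI::dbListFields(con, ann),
                   c("ConceptID", "ConceptLabel", "Level"))[1L]
    keys <- if (length(concept_set)) {
      q <- sprintf("SELECT DISTINCT %s AS k FROM %s WHERE ConceptID IN (%s)%s",
                   quote_id(con, key), quote_id(con, ann),
                   paste(sql_keys(con, concept_set), collapse = ", "),
                   if (!is.na(level_cap))
                     sprintf(" AND Level <= %d", level_cap) else "")
      DBI::dbGetQuery(con, q)$k
    } else NULL
    ref <- if (qualified) paste0(ref_id(con, tbl), ".", ref_id(con, key))
           else ref_id(con, key)
    pieces[[i]] <- if (!length(keys)) {
      sprintf("%s IN (SELECT NULL WHERE 1=0)", ref)
    } else if (length(keys) > max_inline_keys) {
      tmp <- sprintf("osql_keys_%d", next_tmp_id())
      DBI::dbExecute(con, sprintf("DROP TABLE IF EXISTS temp.%s", tmp))
      DBI::dbExecute(con, sprintf("CREATE TEMP TABLE %s (k)", quote_id(con, tmp)))
      DBI::dbAppendTable(con, tmp, data.frame(k = keys))
      sprintf("%s IN (SELECT k FROM %s)", ref, quote_id(con, tmp))
    } else {
      sprintf("%s IN (%s)", ref, paste(sql_keys(con, keys), collapse = ", "))
    }
    counts[[i]] <- length(keys)
    tables[[i]] <- tbl
  }
  clause <- if (length(pieces) > 1L)
    paste0("(", paste(pieces, collapse = " OR "), ")") else pieces[[1L]]
  list(clause = clause,
       targets = data.frame(table = tables, column = expr$targets$column,
                            n_keys = counts, stringsAsFactors = FALSE))
}

## Tables named in FROM/JOIN clauses (outside literals).
from_tables <- function(sql) {
  masked <- mask_literals(sql)
  out <- character()
  m <- gregexpr("(?i)\\bFROM\\s+([A-Za-z_][A-Za-z0-9_]*(\\s*,\\s*[A-Za-z_][A-Za-z0-9_]*)*)",
                masked, perl = TRUE)[[1L]]
  if (m[1L] != -1L) {
    for (txt in regmatches(masked, list(m))[[1L]]) {
      lst <- sub("(?i)^FROM\\s+", "", txt, perl = TRUE)
      out <- c(out, trimws(strsplit(lst, ",", fixed = TRUE)[[1L]]))
    }
  }
  j <- gregexpr("(?i)\\bJOIN\\s+([A-Za-z_][A-Za-z0-9_]*)", masked, perl = TRUE)[[1L]]
  if (j[1L] != -1L)
    out <- c(out, sub("(?i)^JOIN\\s+", "",
                      regmatches(masked, list(j))[[1L]], perl = TRUE))
  unique(out)
}

#' Rewrite an O-SQL query to standard SQL
#'
#' Every embedded O-SQL expression is parsed, resolved against the
#' ontology, converted to an IN-subclause over the matching annotation
#' table(s), and spliced back in place.  All characters outside
#' expression spans are preserved byte for byte, so surrounding SQL —
#' parentheses, `NOT`, `AND`, `OR` — keeps its standard meaning, and each
#' expression is converted independently.
#'
#' @param sql O-SQL query text.
#' @param con DBI connection with annotation tables built.
#' @param ontology An [ontology()].
#' @param config An [annotator_config()].
#' @param max_inline_keys See [build_subclause()].
#' @return Object of class `osql_rewrite`: list with `sql` (the standard
#'   SQL) and `report`, one entry per expression recording the raw
#'   expression, relation/modifier/depth, the resolved query concepts,
#'   the expanded concept-set size and per-target matched-key counts.
#' @export
rewrite_osql <- function(sql, con, ontology, config = annotator_config(),
                         max_inline_keys = 10000L) {
  spans <- extract_expressions(sql)
  tabs <- from_tables(sql)
  default_table <- if (length(tabs) == 1L) tabs else NA
  report <- vector("list", nrow(spans))
  out <- sql
  for (i in rev(seq_len(nrow(spans)))) {
    expr <- parse_expression(spans$raw[[i]])
    res <- resolve_concept_set(expr, ontology, config)
    sub <- build_subclause(con, expr, res$set, default_table, max_inline_keys)
    out <- paste0(substr(out, 1L, spans$start[[i]] - 1L), sub$clause,
                  substring(out, spans$end[[i]] + 1L))
    report[[i]] <- list(
      expression = spans$raw[[i]], relation = expr$relation,
      modifier = expr$modifier, depth = expr$depth, prefix = expr$prefix,
      query = expr$query, query_concepts = res$query_concepts,
      n_concepts = length(res$set), targets = sub$targets,
      depth_on_isA = expr$relation == "isA" && !is.na(expr$depth))
  }
  structure(list(sql = out, report = report), class = "osql_rewrite")
}

#' @export
print.osql_rewrite <- function(x, ...) {
  cat(x$sql, "\n")
  for (r in x$report) {
    cat(sprintf("-- %s => %s%s, %d concept(s) [%s]%s\n",
                r$expression, r$relation,
                if (!is.na(r$modifier)) paste0("{", r$modifier, "}") else "",
                r$n_concepts,
                paste(r$query_concepts$concept_label, collapse = "; "),
                if (isTRUE(r$depth_on_isA))
                  sprintf(" (depth %d limits subsumption generations)", r$depth)
                else ""))
  }
  invisible(x)
}

#' Execute an O-SQL query
#'
#' [rewrite_osql()] followed by execution on the SQL engine.  Engine
#' errors are re-raised with the rewritten query attached for debugging.
#'
#' @inheritParams rewrite_osql
#' @return List with `rows` (result data frame), `report` (see
#'   [rewrite_osql()]) and `sql` (the rewritten query).
#' @examples
#' \dontrun{
#' con <- DBI::dbConnect(RSQLite::SQLite(), "demo.db")
#' ont <- generate_demo_ontology()
#' execute_osql("SELECT * FROM diagnoses WHERE [chd](Diagnosis)", con, ont)
#' }
#' @export
execute_osql <- function(sql, con, ontology, config = annotator_config(),
                         max_inline_keys = 10000L) {
  rw <- rewrite_osql(sql, con, ontology, config, max_inline_keys)
  rows <- tryCatch(
    DBI::dbGetQuery(con, rw$sql),
    error = function(e) osql_db_error(sprintf(
      "SQL engine error: %s\nrewritten query was: %s",
      conditionMessage(e), rw$sql)))
  list(rows = rows, report = rw$report, sql = rw$sql)
}
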