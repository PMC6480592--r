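#' Create a terminology concept
#'
#' A concept is one entry of the terminology: an opaque identifier, a
#' preferred label, and optional synonyms and abbreviations.  Labels and
#' synonyms are free text; matching is always performed on their normalized
#' form (lower case, umlaut/diacritic folding, collapsed whitespace).
#'
#' @param id Opaque non-empty concept identifier (e.g. `"D0009F4"`).
#' @param label Non-empty preferred label.
#' @param synonyms Character vector of synonyms (may be empty).
#' @param abbreviations Character vector of abbreviations (may be empty).
#' @param language IETF language tag, default `"en"`.
#' @return A list of class `osql_concept`.
#' @examples
#' concept("D0009F4", "Bing-Horton syndrome", synonyms = "cluster headache")
#' @export
concept <- function(id, label, synonyms = character(), abbreviations = character(),
                    language = "en") {
  if (!is_string(id) || !nzchar(id))
    osql_parse_error("concept id must be a non-empty string")
  if (!is_string(label) || !nzchar(trimws(label)))
    osql_parse_error(sprintf("concept '%s': preferred label must be non-empty", id))
  synonyms <- as.character(synonyms)
  abbreviations <- as.character(abbreviations)
  if (any(!nzchar(trimws(synonyms))))
    osql_parse_error(sprintf("concept '%s': empty synonym not allowed", id))
  structure(
    list(id = id, label = label, synonyms = synonyms,
         abbreviations = abbreviations, language = language),
    class = "osql_concept"
  )
}

#' Assemble and validate an ontology
#'
#' Builds the in-process terminology used by the annotator and the query
#' rewriter: a set of concepts plus typed edges of kind `isA` (taxonomy,
#' must be acyclic), `partOf` (mereology, cycles tolerated) and `context`
#' (a generic relation specialized by a free-text label such as
#' `"indication"` or `"side effect"`).  A lexical index from every
#' normalized label, synonym and abbreviation to its concept ids is built
#' eagerly, along with isA/partOf adjacency lists used by the traversals.
#'
#' @param concepts List of [concept()] objects.
#' @param edges Data frame with columns `source`, `kind`
#'   (one of `"isA"`, `"partOf"`, `"context"`), `target`, and
#'   `context_label` (required, non-empty, iff `kind == "context"`).
#'   May be `NULL` for an edgeless ontology.
#' @return An object of class `osql_ontology`.
#' @seealso [load_ontology()], [ancestors()], [descendants()],
#'   [part_of_closure()], [context_targets()], [resolve_label()]
#' @export
ontology <- function(concepts = list(), edges = NULL) {
  if (inherits(concepts, "osql_concept")) concepts <- list(concepts)
  ids <- vapply(concepts, function(x) x$id, character(1))
  if (anyDuplicated(ids))
    osql_parse_error(sprintf("duplicate concept id '%s'",
                             ids[duplicated(ids)][1L]))
  names(concepts) <- ids

  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- data.frame(source = character(), kind = character(),
                        context_label = character(), target = character(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (!"context_label" %in% names(edges)) edges$context_label <- NA_character_
    edges <- edges[, c("source", "kind", "context_label", "target")]
  }

  bad_kind <- setdiff(unique(edges$kind), c("isA", "partOf", "context"))
  if (length(bad_kind))
    osql_parse_error(sprintf("unknown edge kind '%s'", bad_kind[1L]))
  dangling <- setdiff(unique(c(edges$source, edges$target)), ids)
  if (length(dangling))
    osql_parse_error(sprintf(
      "edge references unknown concept id '%s'", dangling[1L]))
  is_ctx <- edges$kind == "context"
  if (any(is_ctx & (is.na(edges$context_label) | !nzchar(trimws(edges$context_label)))))
    osql_parse_error("context edge without a context_label")
  if (any(!is_ctx & !is.na(edges$context_label)))
    osql_parse_error("context_label given on a non-context edge")

  isa <- edges[edges$kind == "isA", , drop = FALSE]
  check_isa_acyclic(isa, ids)

  ont <- structure(
    list(
      concepts = concepts,
      edges = edges,
      isa_parents = adjacency(isa$source, isa$target, ids),
      isa_children = adjacency(isa$target, isa$source, ids),
      partof_parts = adjacency(
        edges$target[edges$kind == "partOf"],
        edges$source[edges$kind == "partOf"], ids),
      index = NULL,
      lexicon = NULL
    ),
    class = "osql_ontology"
  )
  ont$index <- build_label_index(ont)
  ont$lexicon <- build_lexicon(ont)
  ont
}

adjacency <- function(from, to, ids) {
  adj <- split(to, factor(from, levels = ids))
  lapply(adj, unique)
}

## Kahn's algorithm; on failure names one concrete cycle found by DFS.
check_isa_acyclic <- function(isa, ids) {
  if (nrow(isa) == 0L) return(invisible(TRUE))
  indeg <- table(factor(isa$target, levels = ids))
  out <- split(isa$target, factor(isa$source, levels = ids))
  queue <- ids[indeg == 0L]
  seen <- 0L
  indeg <- as.integer(indeg); names(indeg) <- ids
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (w in out[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  if (seen < length(ids)) {
    rest <- names(indeg)[indeg > 0L]
    cyc <- find_cycle(isa, rest[1L])
    osql_parse_error(sprintf("isA hierarchy contains a cycle: %s",
                             paste(cyc, collapse = " -> ")))
  }
  invisible(TRUE)
}

find_cycle <- function(isa, start) {
  out <- split(isa$target, isa$source)
  path <- start
  repeat {
    nxt <- out[[path[length(path)]]]
    if (is.null(nxt)) return(path)
    v <- nxt[[1L]]
    if (v %in% path) return(c(path[which(path == v):length(path)], v))
    path <- c(path, v)
  }
}

build_label_index <- function(ont) {
  keys <- character(); ids <- character(); kinds <- character()
  for (cc in ont$concepts) {
    surfaces <- c(cc$label, cc$synonyms, cc$abbreviations)
    kind <- c("label", rep("synonym", length(cc$synonyms)),
              rep("abbreviation", length(cc$abbreviations)))
    keys <- c(keys, vapply(surfaces, norm_phrase, character(1)))
    ids <- c(ids, rep(cc$id, length(surfaces)))
    kinds <- c(kinds, kind)
  }
  keep <- nzchar(keys)
  df <- data.frame(key = keys[keep], id = ids[keep], kind = kinds[keep],
                   stringsAsFactors = FALSE)
  df <- unique(df)
  split(df[c("id", "kind")], df$key)
}

#' Word lexicon of an ontology
#'
#' All words occurring in any normalized label, synonym or abbreviation,
#' with their frequencies.  This is the reference vocabulary for spell
#' correction and compound splitting.
#'
#' @param ontology An [ontology()].
#' @return Named integer vector: word -> frequency.
#' @export
build_lexicon <- function(ontology) {
  words <- unlist(strsplit(names(ontology$index %||%
                                   build_label_index(ontology)), " ",
                           fixed = TRUE))
  tab <- table(words)
  setNames(as.integer(tab), names(tab))
}

#' @export
print.osql_ontology <- function(x, ...) {
  nk <- table(factor(x$edges$kind, levels = c("isA", "partOf", "context")))
  cat(sprintf(
    "<osql_ontology> %d concepts; %d isA, %d partOf, %d context edges\n",
    length(x$concepts), nk[["isA"]], nk[["partOf"]], nk[["context"]]))
  invisible(x)
}

concept_ids <- function(ontology) names(ontology$concepts)

concept_label <- function(ontology, id) {
  vapply(id, function(i) ontology$concepts[[i]]$label, character(1),
         USE.NAMES = FALSE)
}

assert_concept <- function(ontology, id) {
  missing <- setdiff(id, names(ontology$concepts))
  if (length(missing))
    osql_semantic_error(sprintf("unknown concept id '%s'", missing[1L]))
  invisible(TRUE)
}

#' Read an ontology document
#'
#' Two on-disk formats are supported:
#'
#' * **JSON-lines** (the reference dialect): one JSON object per line.
#'   Concept objects carry `id`, `label`, and optional `synonyms`,
#'   `abbreviations`, `language`; edge objects carry `source`,
#'   `kind` (`isA`, `partOf`, `context`), `target`, and `context_label`
#'   for context edges.
#' * **OBO 1.4 subset**: `[Term]` stanzas with `id`, `name`, `synonym`,
#'   `is_a` and `relationship: part_of` lines; `is_a` maps to `isA`,
#'   `part_of` to `partOf`.
#'
#' @param path Path to the document (UTF-8).
#' @param format `"auto"` (default; `.obo` files are read as OBO),
#'   `"jsonl"` or `"obo"`.
#' @return A validated [ontology()].
#' @export
load_ontology <- function(path, format = c("auto", "jsonl", "obo")) {
  format <- match.arg(format)
  if (!file.exists(path))
    osql_db_error(sprintf("ontology file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.obo$", path, ignore.case = TRUE) ||
                  any(grepl("^\\[Term\\]", lines))) "obo" else "jsonl"
  }
  if (format == "obo") parse_obo(lines) else parse_jsonl(lines)
}

parse_jsonl <- function(lines) {
  concepts <- list()
  edges <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    obj <- tryCatch(jsonlite::fromJSON(ln), error = function(e)
      osql_parse_error(sprintf("line %d: invalid JSON: %s", i, conditionMessage(e))))
    if (!is.null(obj$id)) {
      concepts[[length(concepts) + 1L]] <- concept(
        id = obj$id, label = obj$label,
        synonyms = obj$synonyms %||% character(),
        abbreviations = obj$abbreviations %||% character(),
        language = obj$language %||% "en")
    } else if (!is.null(obj$source)) {
      edges[[length(edges) + 1L]] <- data.frame(
        source = obj$source, kind = obj$kind,
        context_label = obj$context_label %||% NA_character_,
        target = obj$target, stringsAsFactors = FALSE)
    } else {
      osql_parse_error(sprintf(
        "line %d: object is neither a concept ('id') nor an edge ('source')", i))
    }
  }
  ontology(concepts, if (length(edges)) do.call(rbind, edges) else NULL)
}

parse_obo <- function(lines) {
  concepts <- list(); edges <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur) || is.null(cur$id)) return(NULL)
    concept(cur$id, cur$name %||% cur$id, synonyms = cur$synonyms %||% character())
  }
  for (i in seq_along(lines)) {
    ln <- trimws(sub("!.*$", "", lines[[i]]))
    if (ln == "[Term]") {
      cc <- flush(cur); if (!is.null(cc)) concepts[[length(concepts) + 1L]] <- cc
      cur <- list(synonyms = character())
      next
    }
    if (grepl("^\\[", ln)) { # other stanza types end the current term
      cc <- flush(cur); if (!is.null(cc)) concepts[[length(concepts) + 1L]] <- cc
      cur <- NULL
      next
    }
    if (is.null(cur) || !nzchar(ln)) next
    kv <- regmatches(ln, regexec("^([a-z_]+):\\s*(.*)$", ln))[[1L]]
    if (length(kv) < 3L) next
    key <- kv[[2L]]; val <- trimws(kv[[3L]])
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "synonym") {
      m <- regmatches(val, regexec('^"([^"]*)"', val))[[1L]]
      if (length(m) == 2L && nzchar(m[[2L]]))
        cur$synonyms <- c(cur$synonyms, m[[2L]])
    } else if (key == "is_a") {
      edges[[length(edges) + 1L]] <- data.frame(
        source = cur$id, kind = "isA", context_label = NA_character_,
        target = strsplit(val, "\\s+")[[1L]][1L], stringsAsFactors = FALSE)
    } else if (key == "relationship") {
      parts <- strsplit(val, "\\s+")[[1L]]
      if (length(parts) >= 2L && parts[[1L]] == "part_of")
        edges[[length(edges) + 1L]] <- data.frame(
          source = cur$id, kind = "partOf", context_label = NA_character_,
          target = parts[[2L]], stringsAsFactors = FALSE)
    }
  }
  cc <- flush(cur); if (!is.null(cc)) concepts[[length(concepts) + 1L]] <- cc
  ontology(concepts, if (length(edges)) do.call(rbind, edges) else NULL)
}

#' Write an ontology in the JSON-lines reference dialect
#'
#' @param ontology An [ontology()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(ontology, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (cc in ontology$concepts) {
    writeLines(jsonlite::toJSON(
      list(id = cc$id, label = cc$label, synonyms = cc$synonyms,
           abbreviations = cc$abbreviations, language = cc$language),
      auto_unbox = TRUE), con)
  }
  e <- ontology$edges
  for (i in seq_len(nrow(e))) {
    obj <- list(source = e$source[[i]], kind = e$kind[[i]], target = e$target[[i]])
    if (!is.na(e$context_label[[i]])) obj$context_label <- e$context_label[[i]]
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), con)
  }
  invisible(path)
}
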