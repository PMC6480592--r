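#' Taxonomy of a concept: all isA ancestors with semantic distance
#'
#' Breadth-first search up the isA hierarchy.  Every reachable ancestor is
#' returned exactly once, at the minimal number of isA edges on any path
#' from the query concept (its "semantic distance", starting at 1 for a
#' direct parent).  The queried concept itself is not included.
#'
#' @param ontology An [ontology()].
#' @param concept_id A concept id present in the ontology.
#' @return Data frame with columns `concept_id`, `level`, ordered by
#'   level ascending then concept id.
#' @export
ancestors <- function(ontology, concept_id) {
  assert_concept(ontology, concept_id)
  level <- bfs_levels(ontology$isa_parents, concept_id)
  level <- level[names(level) != concept_id]
  out <- data.frame(concept_id = names(level), level = as.integer(level),
                    stringsAsFactors = FALSE)
  out <- out[order(out$level, out$concept_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Minimal edge distances from `start` following `adj` (named list id -> ids).
bfs_levels <- function(adj, start) {
  dist <- c(structure(0L, names = start))
  frontier <- start
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, names(dist))
    if (!length(nxt)) break
    dist <- c(dist, structure(rep(d, length(nxt)), names = nxt))
    frontier <- nxt
  }
  dist
}

#' Concepts subsumed by a concept, bounded by generations
#'
#' All concepts from which `concept_id` is reachable via isA edges within
#' `max_generations - 1` edges.  Generations count the query concept as
#' generation 1, so `max_generations = 1` returns the concept itself only
#' and `max_generations = 2` adds its direct isA children.
#'
#' @inheritParams ancestors
#' @param max_generations Positive integer, or `Inf` for the full
#'   subsumption closure.
#' @return Sorted character vector of concept ids (always includes
#'   `concept_id` itself).
#' @export
descendants <- function(ontology, concept_id, max_generations = Inf) {
  assert_concept(ontology, concept_id)
  if (!is.numeric(max_generations) || length(max_generations) != 1L ||
      is.na(max_generations) || max_generations < 1)
    osql_semantic_error("max_generations must be a positive integer or Inf")
  dist <- bfs_levels(ontology$isa_children, concept_id)
  sort(names(dist)[dist <= max_generations - 1])
}

#' Transitive partOf closure
#'
#' All concepts that are parts of `concept_id`, directly or through a
#' chain of partOf edges (parts of parts).  The concept itself is
#' excluded.  partOf graphs may contain cycles; traversal terminates via
#' a visited set.
#'
#' @inheritParams ancestors
#' @return Sorted character vector of concept ids.
#' @export
part_of_closure <- function(ontology, concept_id) {
  assert_concept(ontology, concept_id)
  dist <- bfs_levels(ontology$partof_parts, concept_id)
  sort(setdiff(names(dist), concept_id))
}

#' Targets of labelled context edges
#'
#' The union, over all `source_ids`, of the targets of context edges whose
#' label matches `context_label` case-insensitively with internal
#' whitespace collapsed (e.g. a drug's `"indication"` edges point at the
#' conditions it is indicated for).
#'
#' @inheritParams ancestors
#' @param source_ids Character vector of concept ids.
#' @param context_label Non-empty free-text edge label.
#' @return Sorted character vector of target concept ids.
#' @export
context_targets <- function(ontology, source_ids, context_label) {
  assert_concept(ontology, source_ids)
  if (!is_string(context_label) || !nzchar(trimws(context_label)))
    osql_semantic_error("context_label must be a non-empty string")
  want <- tolower(trimws2(context_label))
  e <- ontology$edges
  hit <- e$kind == "context" &
    tolower(trimws2(e$context_label)) == want &
    e$source %in% source_ids
  sort(unique(e$target[hit]))
}

#' Resolve a normalized label to concept ids
#'
#' Exact lookup in the lexical index: the ids of every concept whose
#' preferred label, synonym or abbreviation normalizes to `text`.
#'
#' @inheritParams ancestors
#' @param text Label text; it is normalized with the annotator rules
#'   before lookup.
#' @return Sorted character vector of concept ids (possibly empty).
#' @export
resolve_label <- function(ontology, text) {
  hit <- ontology$index[[norm_phrase(text)]]
  if (is.null(hit)) character() else sort(unique(hit$id))
}
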