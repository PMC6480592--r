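# Independent oracles and fixture builders shared across tests.

# Random layered DAG: edges only point from lower- to higher-numbered
# concepts, so the isA subset is acyclic by construction.  A share of
# partOf and context edges is added on top.
random_dag_ontology <- function(n, p = 0.08, seed = 1, extra_kinds = TRUE) {
  set.seed(seed)
  ids <- sprintf("N%03d", seq_len(n))
  concepts <- lapply(ids, function(i) concept(i, paste("node", tolower(i))))
  src <- character(); dst <- character(); kind <- character(); lab <- character()
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (stats::runif(1) < p) {
      k <- if (!extra_kinds) "isA" else
        sample(c("isA", "isA", "isA", "partOf", "context"), 1L)
      src <- c(src, ids[[i]]); dst <- c(dst, ids[[j]]); kind <- c(kind, k)
      lab <- c(lab, if (k == "context") sample(c("indication", "side effect"), 1L)
               else NA_character_)
    }
  }
  edges <- if (length(src))
    data.frame(source = src, kind = kind, context_label = lab, target = dst,
               stringsAsFactors = FALSE) else NULL
  ontology(concepts, edges)
}

# BFS shortest-path oracle over the raw isA edge list (igraph).
igraph_ancestor_levels <- function(ont, id) {
  isa <- ont$edges[ont$edges$kind == "isA", c("source", "target")]
  g <- igraph::graph_from_data_frame(isa, directed = TRUE,
                                     vertices = names(ont$concepts))
  d <- igraph::distances(g, v = id, mode = "out")[1L, ]
  d <- d[is.finite(d) & d > 0]
  out <- data.frame(concept_id = names(d), level = as.integer(d),
                    stringsAsFactors = FALSE)
  out[order(out$level, out$concept_id), , drop = FALSE]
}

igraph_descendants <- function(ont, id, max_gen = Inf) {
  isa <- ont$edges[ont$edges$kind == "isA", c("source", "target")]
  g <- igraph::graph_from_data_frame(isa, directed = TRUE,
                                     vertices = names(ont$concepts))
  d <- igraph::distances(g, v = id, mode = "in")[1L, ]
  sort(names(d)[is.finite(d) & d <= max_gen - 1])
}

# Transitive closure of partOf by repeated edge joins on the raw list.
join_partof_closure <- function(ont, id) {
  e <- ont$edges[ont$edges$kind == "partOf", c("source", "target")]
  found <- character()
  frontier <- id
  repeat {
    nxt <- setdiff(e$source[e$target %in% frontier], c(found, id))
    if (!length(nxt)) break
    found <- c(found, nxt)
    frontier <- nxt
  }
  sort(found)
}

# Per-record semantic match table: direct concepts at level 0 plus isA
# ancestors at minimal level, computed without the annotation-table builder.
record_match_table <- function(text, ont, config = annotator_config()) {
  ann <- annotate_text(text, ont, config)
  if (!nrow(ann)) return(data.frame(concept_id = character(), level = integer()))
  direct <- unique(ann$concept_id)
  out <- data.frame(concept_id = direct, level = 0L, stringsAsFactors = FALSE)
  for (d in direct) {
    a <- ancestors(ont, d)
    out <- rbind(out, a)
  }
  stats::aggregate(level ~ concept_id, data = out, FUN = min)
}

# Brute-force evaluation of one O-SQL atom against a match table.
atom_matches <- function(expr, match_tab, ont, config = annotator_config()) {
  set <- resolve_concept_set(expr, ont, config)$set
  hit <- match_tab[match_tab$concept_id %in% set, , drop = FALSE]
  if (expr$relation == "isA" && !is.na(expr$depth))
    hit <- hit[hit$level <= expr$depth - 1L, , drop = FALSE]
  nrow(hit) > 0L
}

# Random well-formed O-SQL atoms/queries over a generated corpus.
random_atom <- function(ont, column) {
  id <- sample(names(ont$concepts), 1L)
  q <- ont$concepts[[id]]$label
  rel <- sample(c("isA", "isA", "partOf", "context"), 1L)
  prefix <- if (stats::runif(1) < 0.3) "+" else ""
  if (rel == "isA") {
    kw <- sample(c("", "isA"), 1L)
    depth <- if (kw == "isA" && stats::runif(1) < 0.25)
      sprintf(":%d", sample.int(4L, 1L)) else ""
    sprintf("%s%s%s[%s](%s)", prefix, kw, depth, q, column)
  } else if (rel == "partOf") {
    sprintf("%spartOf[%s](%s)", prefix, q, column)
  } else {
    mod <- sample(c("indication", "side effect"), 1L)
    depth <- if (stats::runif(1) < 0.6) sprintf(":%d", sample.int(3L, 1L)) else ""
    sprintf("%shasContext{%s}%s[%s](%s)", prefix, mod, depth, q, column)
  }
}

random_query_structure <- function(ont, column) {
  shape <- sample(c("A", "NOT A", "A AND B", "A OR B",
                    "NOT (A OR B)", "A AND NOT B"), 1L)
  atoms <- list(A = random_atom(ont, column), B = random_atom(ont, column))
  list(shape = shape, atoms = atoms)
}

render_query <- function(struct, table) {
  w <- struct$shape
  w <- sub("\\bA\\b", struct$atoms$A, w)
  w <- sub("\\bB\\b", struct$atoms$B, w)
  sprintf("SELECT RecordId FROM %s WHERE %s", table, w)
}

eval_query_structure <- function(struct, match_tab, ont,
                                 config = annotator_config()) {
  a <- atom_matches(parse_expression(struct$atoms$A), match_tab, ont, config)
  b <- atom_matches(parse_expression(struct$atoms$B), match_tab, ont, config)
  switch(struct$shape,
         "A" = a,
         "NOT A" = !a,
         "A AND B" = a && b,
         "A OR B" = a || b,
         "NOT (A OR B)" = !(a || b),
         "A AND NOT B" = a && !b)
}

demo_config <- function() annotator_config(demo_abbreviations())

with_demo_db <- function(fn) {
  con <- DBI::dbConnect(RSQLite::SQLite(), ":memory:")
  on.exit(DBI::dbDisconnect(con))
  ont <- generate_demo_ontology()
  build_demo_db(con, ont)
  fn(con, ont)
}
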