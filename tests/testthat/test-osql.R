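test_that("expressions are located with exact spans", {
  sql <- "SELECT * FROM t WHERE [chd](diag)"
  sp <- extract_expressions(sql)
  expect_equal(nrow(sp), 1L)
  expect_equal(substring(sql, sp$start, sp$end), "[chd](diag)")
  # single-quoted literals shield expressions
  expect_equal(nrow(extract_expressions(
    "SELECT * FROM t WHERE note = '[chd](diag)'")), 0L)
  # the published two-expression query
  prandin <- paste(
    "select * from tableMed, tableDiag where",
    "tableMed.CID = tableDiag.CID and",
    "+partOf[Prandin](tableMed.Drug) and",
    "hasContext{side effect} [repaglinide](tableDiag.Diag)")
  sp2 <- extract_expressions(prandin)
  expect_equal(nrow(sp2), 2L)
  expect_equal(sp2$raw[1], "+partOf[Prandin](tableMed.Drug)")
})

test_that("stray brackets raise a positioned syntax error", {
  err <- expect_error(extract_expressions("SELECT * FROM t WHERE [chd](diag"),
                      class = "osql_parse_error")
  expect_match(conditionMessage(err), "position")
  expect_error(extract_expressions("SELECT a ] FROM t"),
               class = "osql_parse_error")
  expect_error(extract_expressions("WHERE near[x](t.c)"),
               class = "osql_parse_error")
})

test_that("parse_expression decomposes the published expressions", {
  e1 <- parse_expression("hasContext{indication}:5[diabetes](Drug)")
  expect_equal(e1$relation, "context")
  expect_equal(e1$modifier, "indication")
  expect_equal(e1$depth, 5L)
  expect_equal(e1$query, "diabetes")
  expect_true(is.na(e1$targets$table))
  expect_equal(e1$targets$column, "Drug")
  expect_false(e1$prefix)

  e2 <- parse_expression("[free-text query](tablename.columnname)")
  expect_equal(e2$relation, "isA")
  expect_false(e2$prefix)
  expect_true(is.na(e2$modifier) && is.na(e2$depth))
  expect_equal(e2$targets$table, "tablename")
  expect_equal(e2$targets$column, "columnname")

  e3 <- parse_expression("+partOf[Prandin](tableMed.Drug)")
  expect_true(e3$prefix)
  expect_equal(e3$relation, "partOf")

  e4 <- parse_expression("isA[pain](t.a, t.b,u.c)")
  expect_equal(nrow(e4$targets), 3L)
  expect_equal(e4$targets$column, c("a", "b", "c"))
})

test_that("malformed expressions are rejected", {
  expect_error(parse_expression("[  ](t.c)"), class = "osql_parse_error")
  expect_error(parse_expression("[x]()"), class = "osql_parse_error")
  expect_error(parse_expression("partOf{indication}[x](t.c)"),
               class = "osql_parse_error")
  expect_error(parse_expression("hasContext[x](t.c)"),
               class = "osql_parse_error")
  expect_error(parse_expression("hasContext{}[x](t.c)"),
               class = "osql_parse_error")
  expect_error(parse_expression("isA:0[x](t.c)"), class = "osql_parse_error")
  expect_error(parse_expression("[x](a.b.c)"), class = "osql_parse_error")
})

test_that("concept sets follow the relation semantics", {
  ont <- generate_demo_ontology()
  # plain subsumption query: the query concepts themselves
  r1 <- resolve_concept_set(parse_expression("[chd](t.c)"), ont)
  expect_equal(r1$set, "C000001")
  # +partOf includes the product and its agents
  r2 <- resolve_concept_set(parse_expression("+partOf[Prandin](t.c)"), ont)
  expect_setequal(r2$set, c("M000001", "M000002"))
  # context inheritance via depth
  e3 <- parse_expression("hasContext{indication}:2[Analgesic](t.c)")
  expect_setequal(resolve_concept_set(e3, ont)$set, c("P000001", "P000002"))
  e3a <- parse_expression("hasContext{indication}[Analgesic](t.c)")
  expect_equal(resolve_concept_set(e3a, ont)$set, character())
  # unresolvable query text is a hard error
  expect_error(
    resolve_concept_set(parse_expression("[gibberishzz](t.c)"), ont),
    class = "osql_semantic_error")
})

test_that("subclauses enumerate matching keys per target", {
  with_demo_db(function(con, ont) {
    e <- parse_expression("[cephalea](diagnoses.Diagnosis)")
    s <- build_subclause(con, e, resolve_concept_set(e, ont)$set)
    # the cluster-headache record is reached through its level-4 ancestor row
    expect_match(s$clause, "^diagnoses\\.DiagnosisId IN \\(1\\)$")
    expect_equal(s$targets$n_keys, 1L)
    # empty concept set matches no rows
    s0 <- build_subclause(con, e, character())
    n <- DBI::dbGetQuery(con, sprintf(
      "SELECT COUNT(*) AS n FROM diagnoses WHERE %s", s0$clause))$n
    expect_equal(n, 0L)
    # missing annotation table is a named error
    e2 <- parse_expression("[cephalea](diagnoses.Icd)")
    err <- expect_error(build_subclause(con, e2, "H000004"),
                        class = "osql_db_error")
    expect_match(conditionMessage(err), "_diagnoses_Icd")
  })
})

test_that("two-target subclauses equal the per-table union oracle", {
  with_demo_db(function(con, ont) {
    e <- parse_expression("[fever](tableMed.Drug, tableDiag.Diag)")
    s <- build_subclause(con, e, resolve_concept_set(e, ont)$set)
    expect_match(s$clause, "^\\(tableMed\\.MedId IN .* OR tableDiag\\.DiagId IN .*\\)$")
    rows <- DBI::dbGetQuery(con, sprintf(
      "SELECT MedId, DiagId FROM tableMed, tableDiag WHERE %s", s$clause))
    oracle <- DBI::dbGetQuery(con, "SELECT MedId, DiagId FROM tableMed, tableDiag")
    med_fever <- DBI::dbGetQuery(con,
      "SELECT MedId FROM tableMed WHERE Drug LIKE '%Fever%' OR Drug LIKE '%fever%'")$MedId
    diag_fever <- DBI::dbGetQuery(con,
      "SELECT DiagId FROM tableDiag WHERE Diag LIKE '%fever%'")$DiagId
    keep <- oracle$MedId %in% med_fever | oracle$DiagId %in% diag_fever
    expect_equal(rows[order(rows$MedId, rows$DiagId), ],
                 oracle[keep, ][order(oracle$MedId[keep], oracle$DiagId[keep]), ],
                 ignore_attr = TRUE)
  })
})

test_that("rewrite preserves all non-expression bytes", {
  with_demo_db(function(con, ont) {
    sql <- "SELECT Icd , DiagnosisId  FROM diagnoses WHERE ([chd](Diagnosis)) AND 1=1 -- x"
    rw <- rewrite_osql(sql, con, ont)
    expect_match(rw$sql,
      "^SELECT Icd , DiagnosisId  FROM diagnoses WHERE \\(DiagnosisId IN \\([0-9, ]+\\)\\) AND 1=1 -- x$")
    # no O-SQL remains and the report covers every expression
    expect_equal(nrow(extract_expressions(rw$sql)), 0L)
    expect_length(rw$report, 1L)
    # SQL without O-SQL passes through unchanged
    plain <- "SELECT * FROM diagnoses WHERE Icd = 'I25.1'"
    expect_identical(rewrite_osql(plain, con, ont)$sql, plain)
  })
})

test_that("bare targets resolve against a unique FROM table only", {
  with_demo_db(function(con, ont) {
    ok <- rewrite_osql("SELECT * FROM fig3 WHERE [Ibuprofen](Drug)", con, ont)
    expect_match(ok$sql, "NoteId IN")
    expect_error(
      rewrite_osql(paste("SELECT * FROM tableMed, tableDiag WHERE",
                         "[fever](Diag)"), con, ont),
      class = "osql_db_error")
  })
})

test_that("executed rows respect NOT/AND/OR and De Morgan", {
  with_demo_db(function(con, ont) {
    run <- function(sql) sort(execute_osql(sql, con, ont)$rows$DiagnosisId)
    a <- "[cephalea](Diagnosis)"
    b <- "[fever](Diagnosis)"
    base <- "SELECT DiagnosisId FROM diagnoses WHERE %s"
    all_ids <- DBI::dbGetQuery(con, "SELECT DiagnosisId FROM diagnoses")$DiagnosisId
    ra <- run(sprintf(base, a)); rb <- run(sprintf(base, b))
    expect_equal(run(sprintf(base, paste("NOT", a))), setdiff(all_ids, ra))
    expect_equal(run(sprintf(base, paste(a, "OR", b))), sort(union(ra, rb)))
    expect_equal(run(sprintf(base, paste(a, "AND", b))), sort(intersect(ra, rb)))
    expect_equal(
      run(sprintf(base, sprintf("NOT (%s OR %s)", a, b))),
      run(sprintf(base, sprintf("NOT %s AND NOT %s", a, b))))
    # NOT of a never-matching atom selects every row
    expect_equal(run(sprintf(base, "NOT [Prandin](Diagnosis)")), all_ids)
  })
})

test_that("depth-limited context rows grow monotonically and prefix adds rows", {
  with_demo_db(function(con, ont) {
    run <- function(sql) sort(execute_osql(sql, con, ont)$rows$NoteId)
    prev <- integer()
    for (d in 1:4) {
      cur <- run(sprintf(
        "SELECT NoteId FROM fig3 WHERE hasContext{indication}:%d[Analgesic](Drug)", d))
      expect_true(all(prev %in% cur))
      prev <- cur
    }
    with_prefix <- run(
      "SELECT NoteId FROM fig3 WHERE +hasContext{indication}:2[Analgesic](Drug)")
    without <- run(
      "SELECT NoteId FROM fig3 WHERE hasContext{indication}:2[Analgesic](Drug)")
    expect_true(all(without %in% with_prefix))
    expect_true(3 %in% with_prefix)  # the Ibuprofen note itself
  })
})

test_that("execute returns engine rows plus the concept report", {
  with_demo_db(function(con, ont) {
    res <- execute_osql(
      "SELECT COUNT(*) AS n FROM diagnoses WHERE [Prandin](Diagnosis)", con, ont)
    expect_equal(res$rows$n, 0L)
    expect_equal(res$report[[1]]$query_concepts$concept_id, "M000001")
    err <- expect_error(
      execute_osql("SELECT ghost_column FROM diagnoses WHERE [chd](Diagnosis)",
                   con, ont),
      class = "osql_db_error")
    expect_match(conditionMessage(err), "rewritten query")
  })
})

test_that("large key sets switch to a temporary-table join with equal rows", {
  con <- DBI::dbConnect(RSQLite::SQLite(), ":memory:")
  withr::defer(DBI::dbDisconnect(con))
  ont <- generate_demo_ontology()
  DBI::dbExecute(con, "CREATE TABLE t (Id INTEGER PRIMARY KEY, Txt TEXT)")
  DBI::dbAppendTable(con, "t", data.frame(
    Id = 1:20, Txt = rep(c("fever", "sepsis"), 10)))
  build_annotation_table(con, "t", "Txt", ont)
  sql <- "SELECT Id FROM t WHERE [fever](Txt)"
  inline <- execute_osql(sql, con, ont)
  tmp <- execute_osql(sql, con, ont, max_inline_keys = 2L)
  expect_match(tmp$sql, "IN \\(SELECT k FROM")
  expect_setequal(tmp$rows$Id, inline$rows$Id)
})

test_that("random queries match the per-row brute-force evaluator", {
  ont <- generate_demo_ontology()
  corpus <- generate_corpus(ont, 80, noise_config(misspell = 0.05, seed = 9))
  withr::defer(DBI::dbDisconnect(corpus$con))
  build_annotation_table(corpus$con, corpus$table, corpus$column, ont)
  match_tabs <- lapply(corpus$truth$text, record_match_table, ont = ont)
  set.seed(31)
  for (k in 1:20) {
    struct <- random_query_structure(ont, "Diagnosis")
    sql <- render_query(struct, "records")
    got <- sort(execute_osql(sql, corpus$con, ont)$rows$RecordId)
    want <- corpus$truth$record_id[vapply(match_tabs, function(mt)
      eval_query_structure(struct, mt, ont), logical(1))]
    expect_equal(got, sort(want))
  }
})
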