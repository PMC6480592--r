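#' Name of the annotation table for a (table, column) pair
#'
#' Annotation tables follow the fixed naming scheme
#' `"_" + table + "_" + column`.
#'
#' @param table,column Source table and column identifiers.
#' @return Character scalar.
#' @export
annotation_table_name <- function(table, column) {
  paste0("_", table, "_", column)
}

quote_id <- function(con, x) as.character(DBI::dbQuoteIdentifier(con, x))

## Identifier as written in rewritten SQL: plain names stay unquoted so the
## output reads like hand-written SQL ("ID IN (...)").
ref_id <- function(con, x) {
  if (grepl("^[A-Za-z_][A-Za-z0-9_]*$", x)) x else quote_id(con, x)
}

## Single-column primary key of a table, or an explanatory refusal.
primary_key_column <- function(con, table) {
  if (!DBI::dbExistsTable(con, table))
    osql_db_error(sprintf("table '%s' does not exist", table))
  info <- DBI::dbGetQuery(con, sprintf("PRAGMA table_info(%s)",
                                       quote_id(con, table)))
  pk <- info$name[info$pk > 0L][order(info$pk[info$pk > 0L])]
  if (length(pk) == 0L)
    osql_db_error(sprintf(
      "table '%s' has no declared primary key; annotation requires a single-column primary key",
      table))
  if (length(pk) > 1L)
    osql_db_error(sprintf(
      "table '%s' has a composite primary key (%s); annotation requires a single-column primary key",
      table, paste(pk, collapse = ", ")))
  pk
}

#' Build the annotation table for one free-text column
#'
#' Runs [annotate_text()] over every row of `table.column` and
#' materializes the results in a side table named by
#' [annotation_table_name()]: one row per direct concept match at
#' `Level = 0`, plus one row per distinct isA ancestor of any direct
#' concept at its minimal semantic distance.  Each `(record key,
#' ConceptID)` pair is stored once, at the smallest level over all direct
#' concepts of that record.  Rows are linked to the source table by its
#' single-column primary key; the source table itself is never modified.
#' Indexes on `ConceptID` and on the key column are created.
#'
#' @param con A DBI connection (reference engine: RSQLite).
#' @param table,column Source table and free-text column.
#' @param ontology An [ontology()].
#' @param config An [annotator_config()].
#' @param overwrite Drop an existing annotation table first (default TRUE).
#' @return Number of annotation rows written, invisibly a list with
#'   details (`rows`, `level0`, `ancestors`, `table`).
#' @export
build_annotation_table <- function(con, table, column, ontology,
                                   config = annotator_config(),
                                   overwrite = TRUE) {
  key <- primary_key_column(con, table)
  info <- DBI::dbGetQuery(con, sprintf("PRAGMA table_info(%s)",
                                       quote_id(con, table)))
  if (!column %in% info$name)
    osql_db_error(sprintf("column '%s' does not exist in table '%s'",
                          column, table))
  ann_name <- annotation_table_name(table, column)
  if (DBI::dbExistsTable(con, ann_name)) {
    if (!overwrite)
      osql_db_error(sprintf("annotation table '%s' already exists", ann_name))
    DBI::dbRemoveTable(con, ann_name)
  }

  src <- DBI::dbGetQuery(con, sprintf(
    "SELECT %s AS key, %s AS txt FROM %s",
    quote_id(con, key), quote_id(con, column), quote_id(con, table)))

  chunks <- lapply(seq_len(nrow(src)), function(i) {
    ann <- annotate_text(src$txt[[i]], ontology, config)
    if (!nrow(ann)) return(NULL)
    direct <- unique(ann$concept_id)
    rows <- data.frame(key = src$key[[i]], ConceptID = direct,
                       ConceptLabel = concept_label(ontology, direct),
                       Level = 0L, stringsAsFactors = FALSE)
    anc <- do.call(rbind, lapply(direct, function(d) ancestors(ontology, d)))
    if (!is.null(anc) && nrow(anc)) {
      anc <- stats::aggregate(level ~ concept_id, data = anc, FUN = min)
      anc <- anc[!anc$concept_id %in% direct, , drop = FALSE]
      if (nrow(anc))
        rows <- rbind(rows, data.frame(
          key = src$key[[i]], ConceptID = anc$concept_id,
          ConceptLabel = concept_label(ontology, anc$concept_id),
          Level = as.integer(anc$level), stringsAsFactors = FALSE))
    }
    rows
  })
  ann_rows <- do.call(rbind, chunks)
  if (is.null(ann_rows))
    ann_rows <- data.frame(key = src$key[0], ConceptID = character(),
                           ConceptLabel = character(), Level = integer(),
                           stringsAsFactors = FALSE)
  names(ann_rows)[1L] <- key
  DBI::dbWriteTable(con, ann_name, ann_rows)
  safe <- gsub("[^A-Za-z0-9_]", "_", ann_name)
  DBI::dbExecute(con, sprintf("CREATE INDEX %s ON %s (%s)",
                              quote_id(con, paste0("idx", safe, "_concept")),
                              quote_id(con, ann_name), "ConceptID"))
  DBI::dbExecute(con, sprintf("CREATE INDEX %s ON %s (%s)",
                              quote_id(con, paste0("idx", safe, "_key")),
                              quote_id(con, ann_name), quote_id(con, key)))
  invisible(list(rows = nrow(ann_rows),
                 level0 = sum(ann_rows$Level == 0L),
                 ancestors = sum(ann_rows$Level > 0L),
                 table = ann_name))
}

#' Rebuild an annotation table from scratch
#'
#' Drop-and-rebuild; the result is identical to a fresh
#' [build_annotation_table()], which is how schema or ontology changes
#' are propagated.
#'
#' @inheritParams build_annotation_table
#' @return As [build_annotation_table()].
#' @export
refresh_annotations <- function(con, table, column, ontology,
                                config = annotator_config()) {
  build_annotation_table(con, table, column, ontology, config,
                         overwrite = TRUE)
}
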