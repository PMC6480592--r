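#' Deterministic demonstration ontology
#'
#' A small terminology wired to exercise every query mechanism:
#'
#' * a headache taxonomy: Bing-Horton syndrome (synonym "cluster
#'   headache") with a four-edge isA chain up to "cephalea", plus the
#'   auxiliary concepts "two" and "week";
#' * an analgesics fragment: Ibuprofen isA Analgesic, with `indication`
#'   context edges from Ibuprofen to Pain and Fever (so indications of
#'   Analgesic are only found when inheritance depth is at least 2);
#' * a drug-product fragment: repaglinide partOf Prandin, a
#'   `side effect` edge repaglinide -> hypoglycemia, and hyperinsulinism
#'   isA hypoglycemia;
#' * coronary heart disease with abbreviation "chd" and isA descendants;
#' * diabetes mellitus with two isA subtypes carrying `indication` edges
#'   to metformin and repaglinide.
#'
#' @return An [ontology()].
#' @export
generate_demo_ontology <- function() {
  concepts <- list(
    concept("A000001", "Analgesic", synonyms = "analgesics"),
    concept("A000002", "Ibuprofen"),
    concept("P000001", "Pain"),
    concept("P000002", "Fever", synonyms = "pyrexia"),
    concept("D0009F4", "Bing-Horton syndrome",
            synonyms = c("cluster headache", "bing horton syndrome")),
    concept("H000001", "trigeminal autonomic cephalalgia"),
    concept("H000002", "primary headache disorder"),
    concept("H000003", "headache disorder", synonyms = "headache"),
    concept("H000004", "cephalea", synonyms = "cephalgia"),
    concept("Z000002", "two"),
    concept("GA000F8", "week", synonyms = "weeks"),
    concept("M000001", "Prandin"),
    concept("M000002", "repaglinide"),
    concept("M000003", "metformin"),
    concept("P000003", "hypoglycemia"),
    concept("P000004", "hyperinsulinism"),
    concept("C000001", "coronary heart disease",
            synonyms = "coronary artery disease", abbreviations = "chd"),
    concept("C000002", "coronary atherosclerosis"),
    concept("C000003", "ischemic cardiomyopathy"),
    concept("DM00001", "diabetes mellitus", synonyms = "diabetes"),
    concept("DM00002", "type 1 diabetes mellitus"),
    concept("DM00003", "type 2 diabetes mellitus"),
    concept("X000001", "pneumonia"),
    concept("X000002", "asphyxia"),
    concept("X000003", "sepsis neonatorum", synonyms = "sepsis"),
    concept("X000004", "Schwangerenberatung",
            synonyms = "pregnancy advisory")
  )
  edge <- function(s, k, t, lab = NA_character_)
    data.frame(source = s, kind = k, context_label = lab, target = t,
               stringsAsFactors = FALSE)
  edges <- rbind(
    edge("A000002", "isA", "A000001"),
    edge("A000002", "context", "P000001", "indication"),
    edge("A000002", "context", "P000002", "indication"),
    edge("D0009F4", "isA", "H000001"),
    edge("H000001", "isA", "H000002"),
    edge("H000002", "isA", "H000003"),
    edge("H000003", "isA", "H000004"),
    edge("M000002", "partOf", "M000001"),
    edge("M000002", "context", "P000003", "side effect"),
    edge("P000004", "isA", "P000003"),
    edge("C000002", "isA", "C000001"),
    edge("C000003", "isA", "C000001"),
    edge("DM00002", "isA", "DM00001"),
    edge("DM00003", "isA", "DM00001"),
    edge("DM00003", "context", "M000003", "indication"),
    edge("DM00003", "context", "M000002", "indication")
  )
  ontology(concepts, edges)
}

#' Demo abbreviation dictionary
#'
#' @return Named list usable as the `abbreviations` argument of
#'   [annotator_config()]; includes the clinical shorthand
#'   `"schw.brtg"` for "Schwangerenberatung".
#' @export
demo_abbreviations <- function() {
  list(
    "schw.brtg" = "Schwangerenberatung",
    "pneu" = "pneumonia",
    "vc" = "vitium cordis"
  )
}

#' Populate the demonstration database
#'
#' Creates and fills four tables reproducing the worked fixtures: a
#' `diagnoses` table (primary key `DiagnosisId`) whose first row reads
#' "cluster headache for two weeks", drug/diagnosis tables `tableMed` and
#' `tableDiag` joined by a common `CID`, and a `fig3` table whose notes
#' are annotated with Pain and Fever.  Annotation tables for all four
#' free-text columns are built with [build_annotation_table()].
#'
#' @param con DBI connection (e.g. to a fresh SQLite file).
#' @param ontology Ontology used for annotation; defaults to
#'   [generate_demo_ontology()].
#' @param config An [annotator_config()]; defaults to one loaded with
#'   [demo_abbreviations()].
#' @return Invisibly, a character vector of the tables created.
#' @export
build_demo_db <- function(con, ontology = generate_demo_ontology(),
                          config = annotator_config(demo_abbreviations())) {
  DBI::dbExecute(con, "CREATE TABLE diagnoses (
      DiagnosisId INTEGER PRIMARY KEY, PatientId INTEGER, CaseId INTEGER,
      Icd TEXT, Diagnosis TEXT)")
  diag <- data.frame(
    DiagnosisId = 1:6, PatientId = 101:106, CaseId = 201:206,
    Icd = c("G44.0", "I25.1", "I25.1", "R50.9", "E16.2", ""),
    Diagnosis = c("cluster headache for two weeks",
                  "coronary heart disease",
                  "coronary atherosclerosis",
                  "fever since two days",
                  "hyperinsulinism",
                  ""),
    stringsAsFactors = FALSE)
  DBI::dbAppendTable(con, "diagnoses", diag)

  DBI::dbExecute(con, "CREATE TABLE tableMed (
      MedId INTEGER PRIMARY KEY, CID INTEGER, Drug TEXT)")
  DBI::dbAppendTable(con, "tableMed", data.frame(
    MedId = 1:5, CID = c(100L, 101L, 102L, 103L, 104L),
    Drug = c("Prandin", "repaglinide", "metformin", "Ibuprofen", "placebo"),
    stringsAsFactors = FALSE))

  DBI::dbExecute(con, "CREATE TABLE tableDiag (
      DiagId INTEGER PRIMARY KEY, CID INTEGER, Diag TEXT)")
  DBI::dbAppendTable(con, "tableDiag", data.frame(
    DiagId = 1:4, CID = c(100L, 101L, 102L, 103L),
    Diag = c("hyperinsulinism", "hypoglycemia",
             "type 2 diabetes mellitus", "fever"),
    stringsAsFactors = FALSE))

  DBI::dbExecute(con, "CREATE TABLE fig3 (
      NoteId INTEGER PRIMARY KEY, Drug TEXT)")
  DBI::dbAppendTable(con, "fig3", data.frame(
    NoteId = 1:3, Drug = c("Pain", "Fever", "Ibuprofen"),
    stringsAsFactors = FALSE))

  build_annotation_table(con, "diagnoses", "Diagnosis", ontology, config)
  build_annotation_table(con, "tableMed", "Drug", ontology, config)
  build_annotation_table(con, "tableDiag", "Diag", ontology, config)
  build_annotation_table(con, "fig3", "Drug", ontology, config)
  invisible(c("diagnoses", "tableMed", "tableDiag", "fig3"))
}
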