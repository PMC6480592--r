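#' Noise configuration for the corpus generator
#'
#' @param misspell Per-token misspelling probability in `[0,1]`: a
#'   selected token receives one random edit (substitute, transpose,
#'   delete or insert).
#' @param abbrev Probability that an embedded concept which has an
#'   abbreviation is written as the abbreviation instead of its label.
#' @param compound Probability that a multi-word label is written as a
#'   concatenated compound (adjacent alphabetic words joined).
#' @param seed Integer RNG seed; the same seed reproduces the corpus
#'   byte for byte.
#' @return List of class `osql_noise_config`.
#' @export
noise_config <- function(misspell = 0.1, abbrev = 0.2, compound = 0.1,
                         seed = 42L) {
  for (r in c(misspell, abbrev, compound))
    if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0 || r > 1)
      osql_parse_error("noise rates must be in [0, 1]")
  structure(list(misspell = misspell, abbrev = abbrev, compound = compound,
                 seed = as.integer(seed)),
            class = "osql_noise_config")
}

## One random edit operation on a word.
random_edit <- function(word) {
  n <- nchar(word)
  if (n < 2L) return(word)
  op <- sample(c("substitute", "transpose", "delete", "insert"), 1L)
  pos <- sample.int(n, 1L)
  ch <- sample(letters, 1L)
  switch(op,
    substitute = paste0(substr(word, 1L, pos - 1L), ch,
                        substring(word, pos + 1L)),
    transpose = {
      p <- min(pos, n - 1L)
      paste0(substr(word, 1L, p - 1L), substr(word, p + 1L, p + 1L),
             substr(word, p, p), substring(word, p + 2L))
    },
    delete = paste0(substr(word, 1L, pos - 1L), substring(word, pos + 1L)),
    insert = paste0(substr(word, 1L, pos), ch, substring(word, pos + 1L)))
}

#' Concepts eligible for embedding in generated text
#'
#' Concepts whose preferred label consists of tokens of at least 4
#' characters each (short function-word-like labels make poor synthetic
#' diagnoses and are excluded).
#'
#' @param ontology An [ontology()].
#' @return Character vector of concept ids.
#' @export
corpus_concepts <- function(ontology) {
  ok <- vapply(ontology$concepts, function(cc) {
    toks <- normalize_text(cc$label)$token
    length(toks) >= 1L && all(nchar(toks) >= 4L)
  }, logical(1))
  names(ontology$concepts)[ok]
}

#' Default record flags derived from an ontology
#'
#' For each isA root (concept with no isA parents) that has at least one
#' descendant, a binary flag is defined that is true for a record iff the
#' record embeds the root or any of its isA descendants.
#'
#' @param ontology An [ontology()].
#' @return Named list of concept-id sets.
#' @export
default_corpus_flags <- function(ontology) {
  ids <- concept_ids(ontology)
  roots <- ids[vapply(ids, function(i)
    length(ontology$isa_parents[[i]]) == 0L, logical(1))]
  flags <- list()
  for (r in roots) {
    d <- descendants(ontology, r, Inf)
    if (length(d) > 1L) {
      nm <- gsub("[^a-z0-9]+", "_", norm_phrase(concept_label(ontology, r)))
      flags[[nm]] <- d
    }
  }
  flags
}

## Filler vocabulary screened to be Levenshtein distance >= 4 from every
## lexicon word, so spell correction can never cross-map a filler token.
filler_words <- function(ontology) {
  cand <- c("status", "unremarkable", "progressive", "documented",
            "observed", "reported", "recurrent", "suspected", "postnatal",
            "clinical", "course", "followup", "ward", "transferred",
            "newborn", "day", "examination", "finding")
  lex <- names(ontology$lexicon)
  keep <- vapply(cand, function(w)
    all(adist(w, lex) >= 4L), logical(1))
  cand[keep]
}

#' Generate a synthetic annotated-text corpus with ground truth
#'
#' Emulates a table of short clinical narratives: each record embeds one
#' to three concept labels (preferred label or a synonym) in filler text,
#' then perturbs the text per the noise configuration — random single-edit
#' misspellings, substitution of labels by their abbreviations, and
#' concatenation of multi-word labels into compounds.  The ground truth
#' records exactly the embedded concepts, the clean (pre-noise) text, the
#' number of misspelling edits applied, and the binary flags.
#'
#' @param ontology An [ontology()].
#' @param n Number of records (>= 1).
#' @param noise A [noise_config()].
#' @param concepts Concept ids eligible for embedding; defaults to
#'   [corpus_concepts()].
#' @param flags Named list of concept-id sets; defaults to
#'   [default_corpus_flags()].
#' @param db Path for the SQLite database, or `":memory:"` (default).
#' @return List of class `osql_corpus` with elements `con` (open DBI
#'   connection; caller closes), `table` (`"records"`), `column`
#'   (`"Diagnosis"`), `truth` (data frame with `record_id`, `text`,
#'   `clean_text`, `n_misspellings`, list-column `concept_ids`, and one
#'   logical column per flag) and `flags` (the flag definition).
#' @export
generate_corpus <- function(ontology, n, noise = noise_config(),
                            concepts = corpus_concepts(ontology),
                            flags = default_corpus_flags(ontology),
                            db = ":memory:") {
  if (!is.numeric(n) || n < 1L) osql_parse_error("n must be >= 1")
  n <- as.integer(n)
  if (!length(concepts)) osql_parse_error("no eligible concepts to embed")
  set.seed(noise$seed)
  fillers <- filler_words(ontology)
  stopifnot(length(fillers) >= 4L)

  surface_for <- function(id, noisy) {
    cc <- ontology$concepts[[id]]
    if (noisy && length(cc$abbreviations) &&
        stats::runif(1) < noise$abbrev)
      return(sample(cc$abbreviations, 1L))
    surfaces <- c(cc$label, cc$synonyms)
    s <- surfaces[[sample.int(length(surfaces), 1L)]]
    words <- strsplit(s, " ", fixed = TRUE)[[1L]]
    if (noisy && length(words) > 1L && stats::runif(1) < noise$compound) {
      # join runs of purely alphabetic adjacent words
      alpha <- grepl("^[[:alpha:]]+$", words)
      out <- character(); buf <- character()
      for (k in seq_along(words)) {
        if (alpha[[k]]) buf <- c(buf, words[[k]])
        else { if (length(buf)) { out <- c(out, paste(buf, collapse = ""));
                                  buf <- character() }
               out <- c(out, words[[k]]) }
      }
      if (length(buf)) out <- c(out, paste(buf, collapse = ""))
      s <- paste(out, collapse = " ")
    }
    s
  }

  rec <- vector("list", n)
  for (i in seq_len(n)) {
    m <- sample.int(3L, 1L)
    ids <- sample(concepts, m)
    parts <- character()
    for (id in ids)
      parts <- c(parts, sample(fillers, 1L), surface_for(id, noisy = TRUE))
    text <- paste(parts, collapse = " ")
    # misspelling pass over every whitespace token
    words <- strsplit(text, " ", fixed = TRUE)[[1L]]
    hit <- stats::runif(length(words)) < noise$misspell
    edited <- words
    edited[hit] <- vapply(words[hit], random_edit, character(1))
    n_edits <- sum(edited != words)
    rec[[i]] <- list(id = i, text = paste(edited, collapse = " "),
                     clean = text, n_edits = n_edits, ids = sort(ids))
  }

  truth <- data.frame(
    record_id = vapply(rec, `[[`, integer(1), "id"),
    text = vapply(rec, `[[`, character(1), "text"),
    clean_text = vapply(rec, `[[`, character(1), "clean"),
    n_misspellings = vapply(rec, `[[`, integer(1), "n_edits"),
    stringsAsFactors = FALSE)
  truth$concept_ids <- lapply(rec, `[[`, "ids")
  for (f in names(flags))
    truth[[f]] <- vapply(truth$concept_ids, function(ids)
      length(intersect(ids, flags[[f]])) > 0L, logical(1))

  con <- DBI::dbConnect(RSQLite::SQLite(), db)
  DBI::dbExecute(con, "CREATE TABLE records (
      RecordId INTEGER PRIMARY KEY, Diagnosis TEXT, AgeDays INTEGER, Sex TEXT)")
  DBI::dbAppendTable(con, "records", data.frame(
    RecordId = truth$record_id, Diagnosis = truth$text,
    AgeDays = sample.int(28L, n, replace = TRUE),
    Sex = sample(c("f", "m"), n, replace = TRUE),
    stringsAsFactors = FALSE))
  structure(list(con = con, table = "records", column = "Diagnosis",
                 truth = truth, flags = flags, ontology = ontology,
                 noise = noise),
            class = "osql_corpus")
}

#' Write the ground-truth sidecar of a corpus as TSV
#'
#' @param corpus An `osql_corpus`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(corpus, path) {
  df <- corpus$truth
  df$concept_ids <- vapply(df$concept_ids, paste, character(1), collapse = ",")
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

## ------------------------------------------------------------------ eval

#' Evaluation statistics from a confusion matrix
#'
#' Sensitivity, specificity, positive predictive value, prevalence and
#' F-score, each rate with its exact (Clopper-Pearson) binomial 95%
#' confidence interval.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts.
#' @return List of class `osql_eval` with the counts, the rates, `f_score`
#'   and a `ci` list of `(low, high)` pairs.
#' @export
eval_result <- function(tp, fp, tn, fn) {
  if (any(c(tp, fp, tn, fn) < 0)) osql_parse_error("counts must be >= 0")
  rate_ci <- function(x, n) {
    if (n == 0L) return(list(est = NA_real_, ci = c(NA_real_, NA_real_)))
    bt <- stats::binom.test(x, n)
    list(est = x / n, ci = as.numeric(bt$conf.int))
  }
  sens <- rate_ci(tp, tp + fn)
  spec <- rate_ci(tn, tn + fp)
  ppv <- rate_ci(tp, tp + fp)
  prev <- rate_ci(tp + fn, tp + fp + tn + fn)
  f <- if (!is.na(sens$est) && !is.na(ppv$est) && (sens$est + ppv$est) > 0)
    2 * ppv$est * sens$est / (ppv$est + sens$est) else NA_real_
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = sens$est, specificity = spec$est, ppv = ppv$est,
         prevalence = prev$est, f_score = f,
         ci = list(sensitivity = sens$ci, specificity = spec$ci,
                   ppv = ppv$ci, prevalence = prev$ci)),
    class = "osql_eval")
}

#' @export
print.osql_eval <- function(x, ...) {
  pct <- function(est, ci) {
    if (is.na(est)) return("n/a")
    sprintf("%.2f%% (CI 95%%: %.2f-%.2f%%)", 100 * est,
            100 * ci[[1L]], 100 * ci[[2L]])
  }
  cat(sprintf("TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  cat("Sensitivity              ", pct(x$sensitivity, x$ci$sensitivity), "\n")
  cat("Specificity              ", pct(x$specificity, x$ci$specificity), "\n")
  cat("Positive predictive value", pct(x$ppv, x$ci$ppv), "\n")
  cat("Prevalence               ", pct(x$prevalence, x$ci$prevalence), "\n")
  cat(sprintf("F score                   %.2f\n", x$f_score))
  invisible(x)
}

#' Evaluate a predicted record set against a ground-truth flag
#'
#' Confusion counts over all ground-truth records: a record is predicted
#' positive iff its key is in `predicted_keys`, and truly positive iff
#' its flag column is `TRUE`.
#'
#' @param predicted_keys Vector of record keys returned by a query.
#' @param truth Ground-truth data frame (from [generate_corpus()]).
#' @param flag Name of a logical flag column in `truth`.
#' @return An [eval_result()].
#' @export
evaluate_flags <- function(predicted_keys, truth, flag) {
  if (!NROW(truth)) osql_parse_error("empty ground-truth list")
  if (!flag %in% names(truth) || !is.logical(truth[[flag]]))
    osql_semantic_error(sprintf("flag '%s' is not defined in the ground truth",
                                flag))
  pos <- truth[[flag]]
  pred <- truth$record_id %in% predicted_keys
  eval_result(tp = sum(pred & pos), fp = sum(pred & !pos),
              tn = sum(!pred & !pos), fn = sum(!pred & pos))
}

#' Evaluate annotation recovery against corpus ground truth
#'
#' Compares predicted per-record concept sets with the embedded ground
#' truth over the full (record x eligible concept) grid: a pair is a true
#' positive when the concept was embedded and predicted for that record,
#' a true negative when neither, and so on.
#'
#' @param predicted Data frame with columns `record_id`, `concept_id`
#'   (e.g. the `Level = 0` rows of an annotation table).
#' @param truth Ground-truth data frame from [generate_corpus()].
#' @param universe Concept ids forming the negative universe; defaults to
#'   all concept ids appearing in the truth.
#' @return An [eval_result()].
#' @export
evaluate_annotation <- function(predicted, truth,
                                universe = unique(unlist(truth$concept_ids))) {
  tp <- fp <- fn <- 0L
  pred_by_rec <- split(predicted$concept_id, predicted$record_id)
  for (i in seq_len(nrow(truth))) {
    tr <- intersect(truth$concept_ids[[i]], universe)
    pr <- intersect(unique(pred_by_rec[[as.character(truth$record_id[[i]])]]),
                    universe)
    tp <- tp + length(intersect(tr, pr))
    fn <- fn + length(setdiff(tr, pr))
    fp <- fp + length(setdiff(pr, tr))
  }
  total <- nrow(truth) * length(universe)
  eval_result(tp = tp, fp = fp, fn = fn, tn = total - tp - fp - fn)
}
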