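## Text normalization ---------------------------------------------------

## Lower-case + German umlaut/eszett folding + diacritic stripping.
norm_fold <- function(x) {
  x <- tolower(x)
  x <- gsub("ß", "ss", x)
  x <- gsub("ä", "ae", x)
  x <- gsub("ö", "oe", x)
  x <- gsub("ü", "ue", x)
  out <- iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT")
  ifelse(is.na(out), x, out)
}

#' Normalize a phrase for index lookup
#'
#' Tokenizes with [normalize_text()] and joins the normalized tokens with
#' single spaces.  Labels and query strings are both passed through this
#' before any comparison.
#'
#' @param text Character scalar.
#' @return Normalized character scalar (empty if no tokens).
#' @export
norm_phrase <- function(text) {
  paste(normalize_text(text)$token, collapse = " ")
}

#' Tokenize free text
#'
#' Splits text into word tokens, lower-cased with umlaut/diacritic folding
#' (ä→ae, ö→oe, ü→ue, ß→ss).  Punctuation is split off, but periods are
#' retained inside abbreviation-shaped tokens such as `"Schw.brtg"`.
#' Character offsets (0-based, half-open) reference the original text.
#'
#' @param text Character scalar (UTF-8).
#' @return Data frame with columns `token` (normalized form), `start`,
#'   `end`.  Empty input yields zero rows.
#' @export
normalize_text <- function(text) {
  empty <- data.frame(token = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(text) || is.na(text) || !nzchar(text)) return(empty)
  # first alternative keeps internal periods ("schw.brtg"); second is a word
  pat <- "[\\p{L}\\p{N}]+(?:\\.[\\p{L}\\p{N}]+)+|[\\p{L}\\p{N}]+"
  m <- gregexpr(pat, text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(empty)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  tok <- norm_fold(substring(text, starts, starts + lens - 1L))
  data.frame(token = tok, start = starts - 1L, end = starts + lens - 1L,
             stringsAsFactors = FALSE)
}

## Configuration ---------------------------------------------------------

default_edit_threshold <- function(n) {
  ifelse(n <= 4L, 0L, ifelse(n <= 8L, 1L, 2L))
}

default_stopwords <- function() {
  norm_fold(c("for", "of", "with", "and", "or", "the", "a", "an", "in",
              "on", "at", "to", "since",
              "für", "der", "die", "das", "und", "von", "mit", "bei",
              "seit", "nach", "im", "am"))
}

#' Annotator configuration
#'
#' Tunables of the text-to-concept pipeline.
#'
#' @param abbreviations Named list mapping an abbreviation (normalized
#'   automatically) to one or more expansions, or a path readable by
#'   [read_abbreviations()].
#' @param stopwords Character vector; stop-words are skippable inside
#'   multi-word label matching and never emit concepts themselves.
#' @param max_edit_distance Either a single non-negative integer used for
#'   all tokens, or a function of token length.  The default is length
#'   banded: 0 for tokens of up to 4 characters, 1 for 5–8, 2 for 9 or
#'   more, which avoids false corrections of short clinical tokens.
#' @param min_subword Minimum length of a subword accepted when splitting
#'   concatenated compounds (default 4).
#' @param suffixes Suffix-stripping rules approximating stemming; a token
#'   not found in the lexicon is retried with each suffix removed.
#' @return List of class `osql_annotator_config`.
#' @export
annotator_config <- function(abbreviations = list(),
                             stopwords = default_stopwords(),
                             max_edit_distance = NULL,
                             min_subword = 4L,
                             suffixes = c("s", "es", "en", "e")) {
  if (is.character(abbreviations) && length(abbreviations) == 1L)
    abbreviations <- read_abbreviations(abbreviations)
  if (length(abbreviations)) {
    if (is.null(names(abbreviations)) || any(!nzchar(names(abbreviations))))
      osql_parse_error("abbreviation dictionary entries must be named")
    if (any(lengths(abbreviations) == 0L))
      osql_parse_error("abbreviation with no expansion")
    names(abbreviations) <- vapply(names(abbreviations), function(k)
      paste(normalize_text(k)$token, collapse = "."), character(1))
  }
  thr <- max_edit_distance
  if (is.null(thr)) thr <- default_edit_threshold
  else if (is.numeric(thr)) {
    if (thr < 0) osql_parse_error("max_edit_distance must be >= 0")
    thr_val <- as.integer(thr); thr <- function(n) rep(thr_val, length(n))
  }
  structure(
    list(abbreviations = lapply(abbreviations, norm_fold),
         stopwords = norm_fold(stopwords),
         max_edit_distance = thr,
         min_subword = as.integer(min_subword),
         suffixes = suffixes),
    class = "osql_annotator_config"
  )
}

#' Read an abbreviation dictionary
#'
#' Two-column UTF-8 TSV (abbreviation, expansion); multiple rows per
#' abbreviation accumulate alternative expansions.
#'
#' @param path TSV file path.
#' @return Named list of expansion character vectors.
#' @export
read_abbreviations <- function(path) {
  if (!file.exists(path))
    osql_db_error(sprintf("abbreviation dictionary not found: %s", path))
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          encoding = "UTF-8", quote = "",
                          col.names = c("abbreviation", "expansion"))
  split(df$expansion, df$abbreviation)
}

## Pipeline steps --------------------------------------------------------

#' Expand abbreviations per token
#'
#' Each token keeps itself and gains any dictionary expansions (which may
#' be multi-word).  Matching against dictionary keys is case-insensitive
#' on normalized tokens.
#'
#' @param tokens Character vector of normalized tokens, or the data frame
#'   from [normalize_text()].
#' @param config An [annotator_config()].
#' @return List (one element per token) of alternative character vectors;
#'   the first alternative is always the token itself.
#' @export
expand_abbreviations <- function(tokens, config = annotator_config()) {
  if (is.data.frame(tokens)) tokens <- tokens$token
  lapply(tokens, function(t) unique(c(t, config$abbreviations[[t]])))
}

#' Spell-correct a token against a lexicon
#'
#' Candidates within the configured edit distance (plain Levenshtein),
#' ranked by distance, then descending lexicon frequency, then
#' lexicographically.  A token present in the lexicon ranks first with
#' distance 0.
#'
#' @param token Normalized token.
#' @param lexicon Named integer vector from [build_lexicon()] (or a plain
#'   character vector, taken with frequency 1).
#' @param config An [annotator_config()].
#' @return Data frame with columns `word`, `distance`, `freq`; zero rows
#'   when nothing is within the threshold.
#' @export
correct_spelling <- function(token, lexicon, config = annotator_config()) {
  if (is.character(lexicon)) lexicon <- setNames(rep(1L, length(lexicon)), lexicon)
  words <- names(lexicon)
  thr <- config$max_edit_distance(nchar(token))
  if (token %in% words)
    return(data.frame(word = token, distance = 0L,
                      freq = unname(lexicon[[token]]), stringsAsFactors = FALSE))
  empty <- data.frame(word = character(), distance = integer(),
                      freq = integer(), stringsAsFactors = FALSE)
  if (thr < 1L || !length(words)) return(empty)
  cand <- words[abs(nchar(words) - nchar(token)) <= thr]
  if (!length(cand)) return(empty)
  d <- as.integer(adist(token, cand))
  keep <- d <= thr
  if (!any(keep)) return(empty)
  out <- data.frame(word = cand[keep], distance = d[keep],
                    freq = as.integer(lexicon[cand[keep]]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$distance, -out$freq, out$word), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split a concatenated compound into lexicon words
#'
#' German-style compounds ("Schwangerenberatung") are segmented into two
#' or more lexicon words of at least `min_subword` characters.  Segments
#' may also be fuzzy: a part within the edit-distance tolerance of a
#' lexicon word is accepted at the corresponding cost.  A token that is
#' itself a lexicon word is not split (whole-word matches win).
#'
#' @inheritParams correct_spelling
#' @return List of character vectors (the segmentations, as lexicon
#'   words), ordered by fewest parts then total edit distance; each has a
#'   `distance` attribute.  Empty list when no split exists.
#' @export
split_compound <- function(token, lexicon, config = annotator_config()) {
  if (is.character(lexicon)) lexicon <- setNames(rep(1L, length(lexicon)), lexicon)
  words <- names(lexicon)
  if (token %in% words || nchar(token) < 2L * config$min_subword) return(list())
  n <- nchar(token)
  min_len <- config$min_subword
  # memoized segmentations of the suffix starting at position i (1-based)
  memo <- vector("list", n + 1L)
  done <- logical(n + 1L)
  seg <- function(i) {
    if (i > n) return(list(list(parts = character(), dist = 0L)))
    if (done[[i]]) return(memo[[i]])
    res <- list()
    for (j in seq(i + min_len - 1L, n)) {
      part <- substr(token, i, j)
      cands <- if (part %in% words) {
        data.frame(word = part, distance = 0L, stringsAsFactors = FALSE)
      } else {
        cs <- correct_spelling(part, lexicon, config)
        cs <- cs[nchar(cs$word) >= min_len, , drop = FALSE]
        head(cs, 2L)
      }
      if (!nrow(cands)) next
      rest <- seg(j + 1L)
      for (k in seq_len(nrow(cands))) for (r in rest) {
        res[[length(res) + 1L]] <- list(
          parts = c(cands$word[[k]], r$parts),
          dist = cands$distance[[k]] + r$dist)
      }
      if (length(res) > 60L) break
    }
    memo[[i]] <<- res; done[[i]] <<- TRUE
    res
  }
  segs <- Filter(function(s) length(s$parts) >= 2L, seg(1L))
  if (!length(segs)) return(list())
  ord <- order(vapply(segs, function(s) length(s$parts), integer(1)),
               vapply(segs, function(s) s$dist, integer(1)),
               vapply(segs, function(s) paste(s$parts, collapse = " "),
                      character(1)))
  segs <- segs[ord]
  # distinct corrected-word sequences only, each at its minimal cost
  keys <- vapply(segs, function(s) paste(s$parts, collapse = " "), character(1))
  segs <- segs[!duplicated(keys)]
  lapply(segs, function(s) structure(s$parts, distance = s$dist))
}

## Annotation ------------------------------------------------------------

KIND_SCORE <- c(label = 1, synonym = 0.95, abbreviation = 0.9)

## Alternatives for one token: the token itself, abbreviation expansions,
## and (only when the token is out of vocabulary) stem/spell/compound forms.
token_alternatives <- function(token, ontology, config) {
  alts <- data.frame(alt = token, via = "identity", score = 1,
                     stringsAsFactors = FALSE)
  exp <- config$abbreviations[[gsub(" ", ".", token, fixed = TRUE)]] %||%
    config$abbreviations[[token]]
  for (e in exp)
    alts <- rbind(alts, data.frame(alt = norm_phrase(e), via = "abbreviation",
                                   score = 0.9, stringsAsFactors = FALSE))
  lex <- ontology$lexicon
  if (!(token %in% names(lex))) {
    for (suf in config$suffixes) {
      if (endsWith(token, suf)) {
        stem <- substr(token, 1L, nchar(token) - nchar(suf))
        if (stem %in% names(lex))
          alts <- rbind(alts, data.frame(alt = stem, via = "spell-corrected",
                                         score = 0.9, stringsAsFactors = FALSE))
      }
    }
    cs <- correct_spelling(token, lex, config)
    if (nrow(cs)) {
      best <- cs[cs$distance == cs$distance[[1L]], , drop = FALSE]
      best <- head(best, 2L)
      alts <- rbind(alts, data.frame(
        alt = best$word, via = "spell-corrected",
        score = pmax(0.5, 1 - 0.15 * best$distance), stringsAsFactors = FALSE))
    }
    sp <- split_compound(token, lex, config)
    if (length(sp)) {
      s1 <- sp[[1L]]
      alts <- rbind(alts, data.frame(
        alt = paste(s1, collapse = " "), via = "compound-split",
        score = max(0.5, 0.85 - 0.1 * attr(s1, "distance")),
        stringsAsFactors = FALSE))
    }
  }
  unique(alts)
}

## matchKind of a combination of alternatives + the index surface kind.
combo_kind <- function(vias, index_kind) {
  if (any(vias == "compound-split")) return("compound-split")
  if (any(vias == "spell-corrected")) return("spell-corrected")
  if (any(vias == "abbreviation") || index_kind == "abbreviation")
    return("abbreviation")
  if (index_kind == "synonym") return("synonym")
  "exact"
}

#' Annotate free text with ontology concepts
#'
#' The reference annotation pipeline: tokenize and normalize, expand
#' abbreviations, recover out-of-vocabulary tokens by suffix stripping,
#' spell correction and compound splitting, then map token windows onto
#' the ontology's label index by greedy left-to-right longest match.
#' Multi-token labels are preferred over shorter ones; stop-words inside a
#' window are skipped but never emit concepts; each token is consumed by
#' at most one match.  Ties are broken deterministically: longer span,
#' then higher score, then smaller concept id.
#'
#' @param text Character scalar of free text.
#' @param ontology An [ontology()].
#' @param config An [annotator_config()].
#' @return Data frame with one row per concept match: `concept_id`,
#'   `concept_label`, `start`, `end` (0-based half-open covering span in
#'   the original text), `text` (matched original slice), `match_kind`
#'   (one of exact, synonym, abbreviation, spell-corrected,
#'   compound-split) and `score` in (0, 1]; `score == 1` iff the match is
#'   exact.  Matches never overlap.
#' @examples
#' ont <- generate_demo_ontology()
#' annotate_text("cluster headache for two weeks", ont)
#' @export
annotate_text <- function(text, ontology, config = annotator_config()) {
  empty <- data.frame(concept_id = character(), concept_label = character(),
                      start = integer(), end = integer(), text = character(),
                      match_kind = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  toks <- normalize_text(text)
  if (!nrow(toks)) return(empty)
  idx <- ontology$index
  if (!length(idx)) return(empty)
  max_words <- max(lengths(regmatches(names(idx), gregexpr(" ", names(idx)))) ) + 1L
  is_stop <- toks$token %in% config$stopwords
  alts <- lapply(toks$token, token_alternatives, ontology = ontology,
                 config = config)

  n <- nrow(toks)
  out <- list()
  i <- 1L
  while (i <= n) {
    if (is_stop[[i]]) { i <- i + 1L; next }
    matched <- FALSE
    # candidate window ends, longest first; window content excludes stop-words
    for (j in seq(min(n, i + max_words + 2L), i)) {
      if (j > n || is_stop[[j]]) next
      content <- setdiff(seq(i, j), which(is_stop))
      if (length(content) > max_words) next
      cand <- match_window(content, alts, idx)
      if (is.null(cand)) next
      out[[length(out) + 1L]] <- data.frame(
        concept_id = cand$id,
        concept_label = concept_label(ontology, cand$id),
        start = toks$start[[i]], end = toks$end[[j]],
        text = substring(text, toks$start[[i]] + 1L, toks$end[[j]]),
        match_kind = cand$kind, score = cand$score, stringsAsFactors = FALSE)
      i <- j + 1L
      matched <- TRUE
      break
    }
    if (!matched) i <- i + 1L
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Best concept for one token window, or NULL.  Enumerates combinations of
## per-token alternatives (capped) and looks each joined string up in the
## label index.
match_window <- function(content, alts, idx) {
  alt_list <- lapply(alts[content], function(a) head(seq_len(nrow(a)), 4L))
  n_combo <- prod(lengths(alt_list))
  if (n_combo > 200L) alt_list <- lapply(alt_list, function(x) head(x, 2L))
  grid <- expand.grid(alt_list, KEEP.OUT.ATTRS = FALSE)
  best <- NULL
  for (r in seq_len(nrow(grid))) {
    rows <- mapply(function(a, k) a[k, , drop = FALSE], alts[content],
                   as.integer(grid[r, ]), SIMPLIFY = FALSE)
    key <- paste(vapply(rows, function(x) x$alt, character(1)), collapse = " ")
    hit <- idx[[key]]
    if (is.null(hit)) next
    vias <- vapply(rows, function(x) x$via, character(1))
    base <- min(vapply(rows, function(x) x$score, numeric(1)))
    for (h in seq_len(nrow(hit))) {
      kind <- combo_kind(vias, hit$kind[[h]])
      score <- min(base, KIND_SCORE[[hit$kind[[h]]]])
      if (kind == "exact") score <- 1
      cand <- list(id = hit$id[[h]], kind = kind, score = score)
      if (is.null(best) || score > best$score ||
          (score == best$score && cand$id < best$id)) best <- cand
    }
  }
  best
}
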