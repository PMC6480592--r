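test_that("normalize_text tokenizes with offsets into the original text", {
  toks <- normalize_text("Cluster headache, for two weeks")
  expect_equal(toks$token, c("cluster", "headache", "for", "two", "weeks"))
  expect_equal(toks$start[1], 0L)
  expect_equal(toks$end[1], 7L)
  # offsets always slice the original text back out
  orig <- "Cluster headache, for two weeks"
  expect_equal(tolower(substring(orig, toks$start + 1, toks$end)), toks$token)
  expect_equal(nrow(normalize_text("")), 0L)
  expect_equal(nrow(normalize_text(NA_character_)), 0L)
})

test_that("abbreviation-shaped tokens keep their internal period", {
  toks <- normalize_text("Schw.brtg")
  expect_equal(toks$token, "schw.brtg")
  expect_equal(nrow(toks), 1L)
})

test_that("umlauts and eszett fold to their ASCII digraphs", {
  expect_equal(normalize_text("Frühgeburt")$token, "fruehgeburt")
  expect_equal(normalize_text("Größe")$token, "groesse")
  expect_equal(normalize_text("Anämie")$token, "anaemie")
})

test_that("normalization is idempotent on token text", {
  for (txt in c("Cluster headache, for two weeks", "Schw.brtg seit Geburt",
                "Frühgeborenes; Anpassungsstörung!")) {
    once <- normalize_text(txt)$token
    twice <- normalize_text(paste(once, collapse = " "))$token
    expect_equal(twice, once)
  }
})

test_that("expand_abbreviations keeps the token and adds expansions", {
  cfg <- annotator_config(list("schw.brtg" = "Schwangerenberatung",
                               "chd" = "coronary heart disease"))
  alts <- expand_abbreviations(c("schw.brtg", "unlisted", "chd"), cfg)
  expect_true("schwangerenberatung" %in% alts[[1]])
  expect_equal(alts[[2]], "unlisted")
  expect_true("coronary heart disease" %in% alts[[3]])
})

test_that("correct_spelling ranks by distance, frequency, then word", {
  lex <- c(cluster = 3L, clusters = 1L, luster = 1L)
  cfg <- annotator_config(max_edit_distance = 2)
  got <- correct_spelling("clutser", lex, cfg)
  expect_equal(got$word[1], "cluster")
  # independent check of the example's distance
  expect_equal(as.integer(adist("clutser", "cluster")), 2L)
  expect_true(all(got$distance <= 2))
  # in-lexicon token is itself at distance 0
  self <- correct_spelling("cluster", lex, cfg)
  expect_equal(self$word, "cluster")
  expect_equal(self$distance, 0L)
  # beyond threshold: empty
  expect_equal(nrow(correct_spelling("zzzzzzz", lex, cfg)), 0L)
})

test_that("the default edit threshold is banded by token length", {
  lex <- c(pain = 1L, sepsis = 1L, hypoglycemia = 1L)
  cfg <- annotator_config()
  # 4-char token: no correction allowed
  expect_equal(nrow(correct_spelling("pein", lex, cfg)), 0L)
  # 6-char token: one edit allowed
  expect_equal(correct_spelling("sepsjs", lex, cfg)$word, "sepsis")
  # 12-char token: two edits allowed
  expect_equal(as.integer(adist("hipoglicemia", "hypoglycemia")), 2L)
  expect_equal(correct_spelling("hipoglicemia", lex, cfg)$word[1],
               "hypoglycemia")
})

test_that("split_compound segments concatenations into lexicon words", {
  lex <- c(schwangeren = 1L, beratung = 1L)
  segs <- split_compound("schwangerenberatung", lex, annotator_config())
  expect_equal(length(segs), 1L)
  expect_equal(as.character(segs[[1]]), c("schwangeren", "beratung"))
  # a token that is itself a lexicon word is not split
  expect_equal(split_compound("beratung", lex, annotator_config()), list())
})

test_that("random two-word concatenations are recovered (exhaustive oracle)", {
  ont <- generate_demo_ontology()
  lex <- ont$lexicon
  words <- names(lex)[nchar(names(lex)) >= 4]
  set.seed(21)
  for (i in 1:15) {
    pair <- sample(words, 2)
    token <- paste0(pair[1], pair[2])
    if (token %in% names(lex)) next
    segs <- split_compound(token, lex, annotator_config())
    # exhaustive cut-point oracle over 2-part splits
    oracle <- list()
    for (cut in 4:(nchar(token) - 4)) {
      a <- substr(token, 1, cut); b <- substring(token, cut + 1)
      if (a %in% names(lex) && b %in% names(lex))
        oracle[[length(oracle) + 1L]] <- c(a, b)
    }
    exact2 <- Filter(function(s) length(s) == 2 && attr(s, "distance") == 0, segs)
    expect_setequal(vapply(exact2, paste, character(1), collapse = " "),
                    vapply(oracle, paste, character(1), collapse = " "))
    expect_true(paste(pair, collapse = " ") %in%
                  vapply(segs, paste, character(1), collapse = " "))
  }
})

test_that("annotate_text reproduces the worked clinical example", {
  ont <- generate_demo_ontology()
  ann <- annotate_text("cluster headache for two weeks", ont)
  expect_setequal(ann$concept_id, c("D0009F4", "Z000002", "GA000F8"))
  expect_equal(ann$match_kind[ann$concept_id == "D0009F4"], "synonym")
  expect_equal(nrow(annotate_text("", ont)), 0L)
  expect_equal(nrow(annotate_text("nothing matches here", ont)), 0L)
})

test_that("matches never overlap and longest spans win", {
  ont <- generate_demo_ontology()
  texts <- c("coronary heart disease and cluster headache",
             "type 2 diabetes mellitus with hypoglycemia",
             "headache disorder headache")
  for (txt in texts) {
    ann <- annotate_text(txt, ont)
    if (nrow(ann) > 1) {
      ann <- ann[order(ann$start), ]
      expect_true(all(ann$start[-1] >= ann$end[-nrow(ann)]))
    }
  }
  # multi-token label preferred over its single-token parts
  ann <- annotate_text("coronary heart disease", ont)
  expect_equal(ann$concept_id, "C000001")
  expect_equal(ann$match_kind, "exact")
  expect_equal(ann$score, 1)
})

test_that("score is 1 exactly for exact matches", {
  ont <- generate_demo_ontology()
  cfg <- annotator_config(demo_abbreviations())
  for (txt in c("Prandin", "cluster headache", "chd", "Schw.brtg",
                "hypoglycemia", "clutser headache"))  {
    ann <- annotate_text(txt, ont, cfg)
    expect_equal(ann$score == 1, ann$match_kind == "exact")
  }
})

test_that("annotation is deterministic", {
  ont <- generate_demo_ontology()
  cfg <- annotator_config(demo_abbreviations())
  txt <- "clutser headache with pyrexia and Schw.brtg seit two weeks"
  expect_identical(annotate_text(txt, ont, cfg), annotate_text(txt, ont, cfg))
})

test_that("unperturbed unique labels are fully recovered", {
  ont <- generate_demo_ontology()
  for (id in corpus_concepts(ont)) {
    ann <- annotate_text(ont$concepts[[id]]$label, ont)
    expect_true(id %in% ann$concept_id)
  }
})
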