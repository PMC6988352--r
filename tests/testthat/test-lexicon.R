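test_that("packaged lexicons carry the published lemma frequencies", {
  train <- load_packaged_lexicon("train")
  expect_equal(nrow(train), 15)
  expect_equal(train$frequency[train$lemma == "isolate"], 8L)
  expect_equal(train$frequency[train$lemma == "infection"], 5L)
  expect_equal(train$frequency[train$lemma == "strain"], 5L)
  unl <- load_packaged_lexicon("unlabeled")
  expect_equal(unl$frequency[unl$lemma == "strain"], 21256L)
  expect_equal(unl$frequency[unl$lemma == "infection"], 12856L)
  expect_equal(unl$frequency[unl$lemma == "isolate"], 9555L)
  # every training lemma is contained in the unlabeled list; the entries
  # without published frequencies are flagged as placeholders
  expect_true(all(train$lemma %in% unl$lemma))
  expect_equal(sum(unl$placeholder), 7)
  expect_error(load_packaged_lexicon("xyz"))
})

test_that("gazetteer longest match never returns nested spans and agrees
           with an exhaustive matcher", {
  gaz <- c("campylobacter", "campylobacter jejuni", "kingella kingae",
           "mrsa")
  sent <- tibble::tibble(
    sentence = 1L, tid = 1:8,
    surface = c("Isolates", "of", "Campylobacter", "jejuni", "and", "MRSA",
                "were", "typed"),
    lemma = tolower(c("Isolates", "of", "Campylobacter", "jejuni", "and",
                      "MRSA", "were", "typed")),
    upos = c("NOUN", "ADP", "PROPN", "PROPN", "CCONJ", "PROPN", "AUX",
             "VERB"),
    head = c(8L, 3L, 1L, 3L, 6L, 3L, 8L, 0L), deprel = "dep",
    start = 0:7 * 10L, end = 0:7 * 10L + 9L
  )
  hits <- find_bacteria_mentions(sent, gaz)
  expect_equal(nrow(hits), 2)
  expect_setequal(hits$name, c("campylobacter jejuni", "mrsa"))

  # exhaustive oracle: all token windows matching any name, then dominance
  # filtering
  brute <- function(sent, gaz) {
    low <- tolower(sent$surface)
    out <- list()
    for (g in gaz) {
      gt <- strsplit(g, " ")[[1]]
      k <- length(gt)
      for (i in seq_len(max(0, nrow(sent) - k + 1))) {
        if (all(low[i:(i + k - 1)] == gt)) {
          out[[length(out) + 1]] <- c(i, i + k - 1)
        }
      }
    }
    if (length(out) == 0) return(out)
    keep <- vapply(out, function(sp) {
      !any(vapply(out, function(o) {
        o[1] <= sp[1] && o[2] >= sp[2] && !identical(o, sp)
      }, logical(1)))
    }, logical(1))
    unique(out[keep])
  }
  for (seed in 1:6) {
    set.seed(seed)
    words <- sample(c("campylobacter", "jejuni", "kingella", "kingae",
                      "mrsa", "the", "of", "in", "soil"), 12, replace = TRUE)
    s2 <- tibble::tibble(sentence = 1L, tid = seq_along(words),
                         surface = words, lemma = words, upos = "NOUN",
                         head = c(0L, rep(1L, length(words) - 1L)),
                         deprel = "dep",
                         start = seq_along(words) * 10L,
                         end = seq_along(words) * 10L + 9L)
    got <- find_bacteria_mentions(s2, gaz)
    want <- brute(s2, gaz)
    expect_equal(nrow(got), length(want))
    for (sp in want) {
      expect_true(any(got$first_tid == sp[1] & got$last_tid == sp[2]))
    }
  }
})

test_that("trigger patterns collect the published slot fillers", {
  run_mining <- function(text) {
    toks <- triggersieve:::heuristic_parse(text)
    gaz <- c("helicobacter pylori", "vibrio cholerae", "kingella kingae")
    sent <- toks[toks$sentence == 1, ]
    bac <- find_bacteria_mentions(sent, gaz)
    tids <- sent$tid[sent$tid >= bac$first_tid[1] & sent$tid <= bac$last_tid[1]]
    m <- match_trigger_patterns(sent, triggersieve:::mention_head(sent, tids),
                                tids, require_location = FALSE)
    sent$surface[match(unique(m$trigger_tid), sent$tid)]
  }
  expect_true("Elimination" %in%
                run_mining("Elimination of Helicobacter pylori in the antrum was reported."))
  expect_true("bacteremia" %in%
                run_mining("Vibrio cholerae bacteremia in patients was frequent."))
  expect_true("carriage" %in%
                run_mining("Respiratory carriage of Kingella kingae was common."))
})

test_that("no trigger pattern fires without a bacteria anchor", {
  toks <- triggersieve:::heuristic_parse("The patient recovered quickly.")
  gaz <- c("kingella kingae")
  sent <- toks[toks$sentence == 1, ]
  expect_equal(nrow(find_bacteria_mentions(sent, gaz)), 0)
})

test_that("compile_lexicon counts, thresholds and is monotone in
           min_frequency", {
  txt <- "Elimination of Helicobacter pylori in the antrum was reported."
  gaz <- c("helicobacter pylori")
  lex3 <- compile_lexicon(rep(txt, 5), gaz, min_frequency = 3)
  expect_equal(lex3$lemma, "elimination")
  expect_equal(lex3$frequency, 5L)
  expect_equal(nrow(compile_lexicon(rep(txt, 5), gaz, min_frequency = 6)), 0)
  expect_equal(nrow(compile_lexicon("No gazetteer name in here.", gaz)), 0)
  expect_warning(empty <- compile_lexicon(character(0), gaz), "empty corpus")
  expect_equal(nrow(empty), 0)
  # raising the threshold never adds entries
  corpus <- c(rep(txt, 4),
              rep("Respiratory carriage of Helicobacter pylori was common.", 2))
  lemmas_at <- function(k) compile_lexicon(corpus, gaz, min_frequency = k)$lemma
  for (k in 1:5) expect_true(all(lemmas_at(k + 1) %in% lemmas_at(k)))
  # the curated stop classes never survive compilation
  stop_txt <- "An evaluation of Helicobacter pylori in broth was performed."
  expect_false("evaluation" %in% compile_lexicon(stop_txt, gaz)$lemma)
})

test_that("detect_triggers stems tokens onto lexicon lemmas, skips entity
           tokens and ignores lexicon order", {
  doc <- load_paper_examples("ex01")[[1]]
  lex <- load_packaged_lexicon("unlabeled")
  tr <- detect_triggers(doc, lex)
  expect_true("carriage" %in% tr$lemma)
  expect_true("prevalence" %in% tr$lemma)
  # entity-internal tokens never trigger
  al <- doc$alignment
  for (i in seq_len(nrow(tr))) {
    inside <- any(al$sentence == tr$sentence[i] &
                    purrr::map_lgl(al$tids, ~ tr$tid[i] %in% .x))
    expect_false(inside)
  }
  # shuffling the lexicon rows changes nothing
  set.seed(1)
  tr2 <- detect_triggers(doc, lex[sample(nrow(lex)), ])
  expect_equal(tr, tr2)
  # a verb matches a noun lemma via stemming
  doc2 <- simple_doc(
    list(dplyr::bind_rows(tk("Organisms", "NOUN", 2, "nsubj"),
                          tk("persist", "VERB", 0, "root"),
                          tk(".", "PUNCT", 2, "punct")))
  )
  lex2 <- triggersieve:::new_lexicon("persistence", 10L, "custom")
  got <- detect_triggers(doc2, lex2)
  expect_equal(got$surface, "persist")
  expect_equal(got$lemma, "persistence")
  # empty lexicon finds nothing
  expect_equal(nrow(detect_triggers(doc, lex[0, ])), 0)
})

test_that("stem ties resolve to the highest-frequency lemma", {
  doc <- simple_doc(
    list(dplyr::bind_rows(tk("Isolates", "NOUN", 2, "nsubj"),
                          tk("grew", "VERB", 0, "root"),
                          tk(".", "PUNCT", 2, "punct")))
  )
  lex <- load_packaged_lexicon("unlabeled")  # isolate 9555 vs isolation 935
  got <- detect_triggers(doc, lex)
  expect_equal(got$lemma, "isolate")
})
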