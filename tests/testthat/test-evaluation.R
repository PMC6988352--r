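test_that("precision/recall/F1 reproduce the published development-data
           cells at one-decimal rounding", {
  # cross-sentence extraction over gold intra events
  r <- prf(gold = 58, predicted = 40, correct = 17)
  expect_equal(c(r$precision, r$recall, r$f1), c(42.5, 29.3, 34.7))
  # cross-sentence extraction over rule-based intra events
  r <- prf(58, 47, 20)
  expect_equal(c(r$precision, r$recall, r$f1), c(42.6, 34.5, 38.1))
  # full rule-based system, all events
  r <- prf(223, 372, 173)
  expect_equal(c(r$precision, r$recall, r$f1), c(46.5, 77.6, 58.2))
  # gold intra + cross extraction, all events
  r <- prf(223, 205, 182)
  expect_equal(c(r$precision, r$recall, r$f1), c(88.8, 81.6, 85.0))
  # remaining published strata
  r <- prf(165, 325, 153)
  expect_equal(c(r$precision, r$recall, r$f1), c(47.1, 92.7, 62.4))
  r <- prf(223, 165, 165)
  expect_equal(c(r$precision, r$recall, r$f1), c(100.0, 74.0, 85.1))
})

test_that("degenerate counts follow the zero-denominator convention and
           invalid counts are rejected", {
  expect_equal(unlist(prf(10, 10, 10)[, c("precision", "recall", "f1")]),
               c(precision = 100, recall = 100, f1 = 100))
  expect_equal(unlist(prf(5, 0, 0)[, c("precision", "recall", "f1")]),
               c(precision = 0, recall = 0, f1 = 0))
  expect_equal(prf(0, 0, 0)$f1, 0)
  expect_error(prf(5, 5, 6), "invalid counts")
  expect_error(prf(-1, 5, 0), "invalid counts")
})

test_that("F1 lies between precision and recall when both are positive", {
  set.seed(42)
  for (k in 1:50) {
    g <- sample(1:50, 1); p <- sample(1:50, 1)
    c0 <- sample(0:min(g, p), 1)
    r <- prf(g, p, c0)
    if (r$precision > 0 && r$recall > 0) {
      expect_lte(r$f1, max(r$precision, r$recall) + 0.05)
      expect_gte(r$f1, min(r$precision, r$recall) - 0.05)
    }
  }
})

test_that("event matching honours Equiv sets and deduplicates pairs", {
  pred <- tibble::tibble(bacteria_id = "B1", location_id = "L2")
  ref <- tibble::tibble(bacteria_id = "B1", location_id = "L1")
  expect_equal(match_events(pred, ref, equiv = list(c("L1", "L2"))), 1)
  expect_equal(match_events(pred, ref), 0)
  # identical sets of size n are all correct
  ids <- tibble::tibble(bacteria_id = paste0("B", 1:4),
                        location_id = paste0("L", 1:4))
  expect_equal(match_events(ids, ids), 4)
  # duplicated predictions count once
  expect_equal(match_events(dplyr::bind_rows(pred, pred), ref,
                            equiv = list(c("L1", "L2"))), 1)
  expect_error(match_events(pred, ref, known_ids = c("B1", "L1")),
               "dangling")
})

test_that("event matching agrees with a brute-force all-pairs oracle under
           random Equiv partitions", {
  brute <- function(pred, ref, equiv) {
    canon <- function(x) {
      for (set in equiv) if (x %in% set) return(min(set))
      x
    }
    pk <- unique(vapply(seq_len(nrow(pred)), function(i) {
      paste(canon(pred$bacteria_id[i]), canon(pred$location_id[i]))
    }, character(1)))
    hits <- 0
    for (p in pk) {
      ok <- FALSE
      for (j in seq_len(nrow(ref))) {
        if (identical(p, paste(canon(ref$bacteria_id[j]),
                               canon(ref$location_id[j])))) ok <- TRUE
      }
      hits <- hits + ok
    }
    hits
  }
  set.seed(7)
  bs <- paste0("B", 1:5); ls <- paste0("L", 1:5)
  for (k in 1:20) {
    pred <- tibble::tibble(bacteria_id = sample(bs, 4, TRUE),
                           location_id = sample(ls, 4, TRUE))
    ref <- tibble::tibble(bacteria_id = sample(bs, 3, TRUE),
                          location_id = sample(ls, 3, TRUE))
    equiv <- list()
    if (k %% 2 == 0) equiv <- list(sample(bs, 2), sample(ls, 2))
    expect_equal(match_events(pred, ref, equiv), brute(pred, ref, equiv),
                 label = paste("case", k))
  }
})

test_that("events stratify by shared sentence index", {
  doc <- load_paper_examples("ex01")[[1]]
  ev <- stratify_events(doc, tibble::tibble(bacteria_id = "T1",
                                            location_id = "T2",
                                            provenance = "x"))
  expect_equal(ev$sentence_span, "cross")
  doc2 <- load_paper_examples("t6r3")[[1]]
  ev2 <- stratify_events(doc2, doc2$gold_events)
  expect_true(all(ev2$sentence_span == "intra"))
  # oracle over the generated corpus
  for (doc3 in generate_corpus(fixture_config(seed = 23, n_docs = 8))) {
    ev3 <- stratify_events(doc3, doc3$gold_events)
    al <- doc3$alignment
    for (i in seq_len(nrow(ev3))) {
      bs <- al$sentence[al$id == ev3$bacteria_id[i]]
      ls <- al$sentence[al$id == ev3$location_id[i]]
      expect_equal(ev3$sentence_span[i], if (bs == ls) "intra" else "cross")
    }
  }
})

test_that("evaluate_events aggregates counts over documents and strata", {
  docs <- generate_corpus(fixture_config(seed = 29, n_docs = 10))
  cfg <- pipeline_config(lexicon = "unlabeled")
  preds <- lapply(docs, function(d) extract_events(d, cfg)$events)
  rep <- evaluate_events(docs, preds)
  expect_s3_class(rep, "eval_report")
  expect_setequal(rep$stratum, c("intra", "cross", "all"))
  all_row <- rep[rep$stratum == "all", ]
  expect_equal(all_row$gold,
               sum(vapply(docs, function(d) nrow(d$gold_events), numeric(1))))
  for (i in 1:3) {
    expect_lte(rep$correct[i], min(rep$gold[i], rep$predicted[i]))
    expect_true(all(unlist(rep[i, c("precision", "recall", "f1")]) >= 0))
    expect_true(all(unlist(rep[i, c("precision", "recall", "f1")]) <= 100))
  }
  # glance surfaces the overall scores
  g <- glance(rep)
  expect_equal(g$f1, all_row$f1)
})
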