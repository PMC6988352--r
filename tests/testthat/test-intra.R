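# Intra-clause patterns, trigger linking, cross-clause inference and the
# propagation fixpoint.

test_that("each intra-clause pattern extracts its characteristic event", {
  cfg <- fixture_config(seed = 5, n_docs = 3)
  for (tpl in c("P1", "P2", "P3", "N1", "N2", "N3")) {
    cfg$template_mix <- stats::setNames(1, tpl)
    for (doc in generate_corpus(cfg)) {
      ev <- extract_intra_clause(doc)
      expect_true(nrow(ev) >= 1, label = tpl)
      expect_true(any(grepl(paste0("intra:", tpl), ev$provenance)) ||
                    tpl %in% c("P1", "P2", "P3"),
                  label = paste(tpl, "provenance"))
      expect_setequal(paste(ev$bacteria_id, ev$location_id),
                      paste(doc$gold_events$bacteria_id,
                            doc$gold_events$location_id))
    }
  }
})

test_that("mentions in different sentences never form an intra-clause
           event", {
  doc <- generate_corpus(fixture_config(
    seed = 2, n_docs = 1,
    template_mix = c(cross_trigger = 1)))[[1]]
  expect_equal(nrow(extract_intra_clause(doc)), 0)
})

test_that("triggers link to the word-distance-nearest bacteria, ties to the
           preceding mention", {
  # single bacteria: all triggers link to it
  doc <- load_paper_examples("ex01")[[1]]
  tr <- detect_triggers(doc, load_packaged_lexicon("unlabeled"))
  linked <- link_triggers(doc, tr, scope = "cross")
  expect_true(all(linked$linked_bacteria == "T1"))
  # constructed tie: trigger exactly between two bacteria
  doc2 <- simple_doc(
    list(dplyr::bind_rows(
      tk("Kingella", "PROPN", 3, "nsubj"),
      tk("kingae", "PROPN", 1, "flat"),
      tk("showed", "VERB", 0, "root"),
      tk("strong", "ADJ", 5, "amod"),
      tk("growth", "NOUN", 3, "obj"),
      tk("unlike", "ADP", 8, "case"),
      tk("Vibrio", "PROPN", 3, "obl"),
      tk("salmonicida", "PROPN", 7, "flat"))),
    entities = list(list(id = "T1", type = "Bacteria", sentence = 1,
                         from = 1, to = 2),
                    list(id = "T2", type = "Bacteria", sentence = 1,
                         from = 7, to = 8))
  )
  tr2 <- detect_triggers(doc2, load_packaged_lexicon("unlabeled"))
  expect_equal(tr2$surface, "growth")  # two words from each mention edge? no:
  linked2 <- link_triggers(doc2, tr2, scope = "intra")
  # one token between T1 and growth ("showed"+"strong" = 2) vs one ("unlike")
  expect_equal(linked2$linked_bacteria, "T2")
  # no bacteria in sentence: unlinked at intra scope
  doc3 <- simple_doc(
    list(dplyr::bind_rows(tk("The", "DET", 2, "det"),
                          tk("growth", "NOUN", 3, "nsubj"),
                          tk("continued", "VERB", 0, "root")))
  )
  tr3 <- detect_triggers(doc3, load_packaged_lexicon("unlabeled"))
  expect_true(all(is.na(link_triggers(doc3, tr3,
                                      scope = "intra")$linked_bacteria)))
})

test_that("equidistant triggers prefer the preceding bacteria mention", {
  doc <- simple_doc(
    list(dplyr::bind_rows(
      tk("Kingella", "PROPN", 3, "nsubj"),
      tk("then", "ADV", 3, "advmod"),
      tk("growth", "NOUN", 0, "root"),
      tk("near", "ADP", 5, "case"),
      tk("Vibrio", "PROPN", 3, "nmod"))),
    entities = list(list(id = "T1", type = "Bacteria", sentence = 1,
                         from = 1, to = 1),
                    list(id = "T2", type = "Bacteria", sentence = 1,
                         from = 5, to = 5))
  )
  tr <- detect_triggers(doc, load_packaged_lexicon("unlabeled"))
  linked <- link_triggers(doc, tr, scope = "intra")
  expect_equal(linked$linked_bacteria, "T1")  # 1 word either side; preceding
})

test_that("cross-clause inference emits events by trigger transitivity", {
  # one-bacteria sentence with triggers reaching two locations
  doc <- simple_doc(
    list(dplyr::bind_rows(
      tk("Kingella", "PROPN", 6, "nsubj"),
      tk("kingae", "PROPN", 1, "flat"),
      tk(",", "PUNCT", 6, "punct"),
      tk("a", "DET", 5, "det"),
      tk("pathogen", "NOUN", 6, "nsubj"),
      tk("persists", "VERB", 0, "root"),
      tk("in", "ADP", 9, "case"),
      tk("young", "ADJ", 9, "amod"),
      tk("children", "NOUN", 5, "nmod"),
      tk(".", "PUNCT", 6, "punct"))),
    entities = list(list(id = "T1", type = "Bacteria", sentence = 1,
                         from = 1, to = 2),
                    list(id = "T2", type = "Habitat", sentence = 1,
                         from = 8, to = 9))
  )
  tr <- detect_triggers(doc, load_packaged_lexicon("unlabeled"))
  expect_true("pathogen" %in% tr$lemma)
  linked <- link_triggers(doc, tr, scope = "intra")
  ev <- infer_cross_clause(doc, linked)
  expect_true(any(ev$bacteria_id == "T1" & ev$location_id == "T2"))
  expect_true(any(grepl("^cross_clause:", ev$provenance)))
  # no triggers -> no additional events
  ev0 <- infer_cross_clause(doc, linked[0, ],
                            intra_events = triggersieve:::empty_events())
  expect_equal(nrow(ev0), 0)
})

test_that("propagation closes each of the five relations over its fixture", {
  cfg <- fixture_config(seed = 9, n_docs = 2)
  for (tpl in c("R1", "R2", "R3", "R4", "R5")) {
    cfg$template_mix <- stats::setNames(1, tpl)
    for (doc in generate_corpus(cfg)) {
      seed_ev <- extract_intra_clause(doc)
      closed <- propagate(doc, seed_ev)
      expect_setequal(paste(closed$bacteria_id, closed$location_id),
                      paste(doc$gold_events$bacteria_id,
                            doc$gold_events$location_id))
      expect_true(any(grepl(paste0("prop:", tpl), closed$provenance)),
                  label = tpl)
    }
  }
})

test_that("the apposition snippet expands one seed event to four", {
  doc <- load_paper_examples("t6r3")[[1]]
  seed_ev <- tibble::tibble(bacteria_id = "T1", location_id = "T3",
                            provenance = "seed")
  closed <- propagate(doc, seed_ev)
  expect_equal(nrow(closed), 4)
  expect_setequal(paste(closed$bacteria_id, closed$location_id),
                  c("T1 T3", "T2 T3", "T1 T4", "T2 T4"))
})

test_that("propagation is idempotent, order-independent and bounded", {
  corpus <- generate_corpus(fixture_config(
    seed = 21, n_docs = 8,
    template_mix = c(R1 = 1, R2 = 1, R3 = 1, R4 = 1, R5 = 1)))
  for (doc in corpus) {
    seed_ev <- extract_intra_clause(doc)
    rel <- triggersieve:::propagation_relations(doc)
    once <- propagate(doc, seed_ev, relations = rel)
    twice <- propagate(doc, once, relations = rel)
    expect_setequal(paste(twice$bacteria_id, twice$location_id),
                    paste(once$bacteria_id, once$location_id))
    # randomized relation orderings reach the same fixpoint
    for (k in 1:3) {
      set.seed(k)
      shuffled <- rel[sample(nrow(rel)), ]
      alt <- propagate(doc, seed_ev, relations = shuffled)
      expect_setequal(paste(alt$bacteria_id, alt$location_id),
                      paste(once$bacteria_id, once$location_id))
    }
    # bounded by |B| x |L|
    nb <- length(triggersieve:::bacteria_ids(doc))
    nl <- length(triggersieve:::location_ids(doc))
    expect_lte(nrow(once), nb * nl)
    # every emitted event carries a provenance label
    expect_true(all(nzchar(once$provenance)))
  }
})

test_that("propagation fixpoint equals a naive single-rule closure oracle", {
  corpus <- generate_corpus(fixture_config(
    seed = 33, n_docs = 6,
    template_mix = c(R1 = 1, R3 = 1, R5 = 1)))
  for (doc in corpus) {
    seed_ev <- extract_intra_clause(doc)
    rel <- triggersieve:::propagation_relations(doc)
    btype <- stats::setNames(doc$entities$type == "Bacteria",
                             doc$entities$id)
    # oracle: keep applying one applicable relation at a time until stuck
    pairs <- unique(paste(seed_ev$bacteria_id, seed_ev$location_id))
    repeat {
      added <- FALSE
      for (k in seq_len(nrow(rel))) {
        for (p in pairs) {
          bl <- strsplit(p, " ")[[1]]
          cand <- if (btype[[rel$from[k]]] && bl[1] == rel$from[k]) {
            paste(rel$to[k], bl[2])
          } else if (!btype[[rel$from[k]]] && bl[2] == rel$from[k]) {
            paste(bl[1], rel$to[k])
          }
          if (!is.null(cand) && !(cand %in% pairs)) {
            pairs <- c(pairs, cand)
            added <- TRUE
          }
        }
      }
      if (!added) break
    }
    closed <- propagate(doc, seed_ev, relations = rel)
    expect_setequal(paste(closed$bacteria_id, closed$location_id), pairs)
  }
})
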