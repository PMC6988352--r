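test_that("CoNLL-U parses load with offsets recovered from the text", {
  text <- "K. kingae persists in children."
  cl <- c("1\tK.\tk.\tPROPN\t_\t_\t3\tnsubj\t_\t_",
          "2\tkingae\tkingae\tPROPN\t_\t_\t1\tflat\t_\t_",
          "3\tpersists\tpersist\tVERB\t_\t_\t0\troot\t_\t_",
          "4\tin\tin\tADP\t_\t_\t5\tcase\t_\t_",
          "5\tchildren\tchild\tNOUN\t_\t_\t3\tobl\t_\t_",
          "6\t.\t.\tPUNCT\t_\t_\t3\tpunct\t_\t_")
  toks <- read_conllu(cl, text)
  expect_equal(toks$start, c(0, 3, 10, 19, 22, 30))
  expect_equal(toks$end, c(2, 9, 18, 21, 30, 31))
  expect_equal(toks$lemma[5], "child")
  expect_error(read_conllu("1\tonly three", text), "malformed")
})

test_that("single-token document analyzes to one sentence rooted at it", {
  doc <- read_document("Bacteremia", character(0), text_is_literal = TRUE)
  doc <- analyze(doc, backend = "heuristic")
  expect_equal(nrow(doc$tokens), 1)
  expect_equal(doc$tokens$head, 0L)
  expect_equal(doc$tokens$sentence, 1L)
})

test_that("a mention crossing a predicted sentence boundary forces a merge", {
  text <- "Bacteria E. Coli was found in soil. Results followed."
  a1 <- "T1\tBacteria 9 16\tE. Coli"
  doc <- read_document(text, a1, text_is_literal = TRUE)
  doc <- analyze(doc, backend = "heuristic")
  # the abbreviation dot would have split the sentence; the mention must
  # end up inside exactly one sentence
  al <- doc$alignment
  expect_equal(nrow(al), 1)
  covered <- doc$tokens[doc$tokens$sentence == al$sentence &
                          doc$tokens$tid %in% al$tids[[1]], ]
  expect_true(all(c("E", "Coli") %in% covered$surface))
  # and the remaining text still forms its own sentence
  expect_gte(max(doc$tokens$sentence), 2)
})

test_that("is_descendant agrees with a transitive-closure oracle and is a
           strict partial order along head chains", {
  for (seed in 1:8) {
    sent <- random_parse(12, seed = seed)
    reach <- ancestor_matrix(sent)
    for (a in sent$tid) {
      expect_false(is_descendant(sent, a, a))  # irreflexive
      for (b in sent$tid) {
        expect_identical(is_descendant(sent, a, b), reach[a, b],
                         label = sprintf("seed %d: %d under %d", seed, a, b))
      }
    }
    # transitivity spot check via the oracle
    trip <- which(reach, arr.ind = TRUE)
    for (k in seq_len(min(nrow(trip), 20))) {
      a <- trip[k, 1]; b <- trip[k, 2]
      cc <- which(reach[b, ])
      for (c2 in cc) expect_true(is_descendant(sent, a, c2))
    }
  }
})

test_that("same_clause matches a path-label oracle and is symmetric", {
  boundary <- c("ccomp", "xcomp", "advcl", "acl", "acl:relcl", "csubj",
                "csubj:pass", "parataxis")
  oracle <- function(sent, a, b) {
    if (a == b) return(TRUE)
    g <- igraph::graph_from_data_frame(
      data.frame(from = sent$tid[sent$head != 0],
                 to = sent$head[sent$head != 0],
                 rel = sent$deprel[sent$head != 0],
                 child = sent$tid[sent$head != 0]),
      directed = FALSE, vertices = data.frame(name = sent$tid)
    )
    p <- igraph::shortest_paths(g, as.character(a), as.character(b),
                                output = "epath")$epath[[1]]
    rels <- igraph::edge_attr(g, "rel", p)
    kids <- igraph::edge_attr(g, "child", p)
    if (any(rels %in% boundary)) return(FALSE)
    verb_conj <- rels == "conj" &
      sent$upos[match(kids, sent$tid)] == "VERB"
    !any(verb_conj)
  }
  for (seed in 1:8) {
    sent <- random_parse(10, seed = seed + 100)
    for (a in sent$tid) {
      for (b in sent$tid) {
        expect_identical(same_clause(sent, a, b), oracle(sent, a, b),
                         label = sprintf("seed %d: %d~%d", seed, a, b))
        expect_identical(same_clause(sent, a, b), same_clause(sent, b, a))
      }
    }
  }
})

test_that("word_distance counts tokens strictly between mentions and
           sentence offsets", {
  doc <- load_paper_examples("ex01")[[1]]
  d <- word_distance(doc, "T1", "T2")
  # T1 ends at sentence-1 token 10; T2 is sentence-2 token 4:
  # tokens 11,12 of s1 and 1,2,3 of s2 lie between
  expect_equal(d$words, 5)
  expect_equal(d$sentences, 1)
  # brute force over random mention placements in a flat layout
  for (seed in 1:5) {
    set.seed(seed)
    n_sent <- 4
    doc2 <- layout_doc(sample(1:n_sent, 2), n_sent)
    al <- doc2$alignment
    flat <- doc2$tokens
    gpos <- function(id) {
      a <- al[al$id == id, ]
      which(flat$sentence == a$sentence & flat$tid %in% a$tids[[1]])
    }
    p1 <- gpos("T1"); p2 <- gpos("T2")
    expected <- if (min(p1) < min(p2)) min(p2) - max(p1) - 1 else
      min(p1) - max(p2) - 1
    d2 <- word_distance(doc2, "T1", "T2")
    expect_equal(d2$words, max(0, expected))
  }
})

test_that("adjacent mentions have zero words between them", {
  doc <- simple_doc(
    list(dplyr::bind_rows(tk("Kingella", "PROPN", 3, "compound"),
                          tk("children", "NOUN", 3, "nsubj"),
                          tk("played", "VERB", 0, "root"))),
    entities = list(list(id = "T1", type = "Bacteria", sentence = 1,
                         from = 1, to = 1),
                    list(id = "T2", type = "Habitat", sentence = 1,
                         from = 2, to = 2))
  )
  expect_equal(word_distance(doc, "T1", "T2")$words, 0)
})

test_that("every mention aligns to one sentence with its head inside it", {
  for (doc in generate_corpus(fixture_config(seed = 3, n_docs = 10))) {
    al <- doc$alignment
    expect_equal(nrow(al), nrow(doc$entities))
    for (i in seq_len(nrow(al))) {
      expect_true(al$head_tid[i] %in% al$tids[[i]])
    }
  }
})
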