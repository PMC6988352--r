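# Shared fixture builders for the test suite.

tk <- function(surface, upos, head, deprel, glue = FALSE) {
  tibble::tibble(surface = surface, upos = upos, head = as.integer(head),
                 deprel = deprel, glue = glue)
}

# a random dependency tree over n tokens (rooted at 1), as a one-sentence
# tokens tibble
random_parse <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  heads <- c(0L, vapply(2:n, function(i) sample.int(i - 1L, 1), integer(1)))
  rels <- c("root", sample(c("nsubj", "obj", "nmod", "amod", "compound",
                             "obl", "advcl", "ccomp", "acl", "conj", "det",
                             "case"), n - 1, replace = TRUE))
  upos <- sample(c("NOUN", "VERB", "ADJ", "ADP", "DET"), n, replace = TRUE)
  tibble::tibble(sentence = 1L, tid = seq_len(n),
                 surface = paste0("w", seq_len(n)),
                 lemma = paste0("w", seq_len(n)), upos = upos,
                 head = heads, deprel = rels,
                 start = (seq_len(n) - 1L) * 3L, end = (seq_len(n) - 1L) * 3L + 2L)
}

# ancestor matrix by transitive closure of the parent relation (oracle for
# is_descendant)
ancestor_matrix <- function(sent) {
  n <- nrow(sent)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    if (sent$head[i] != 0L) adj[i, sent$head[i]] <- TRUE
  }
  reach <- adj
  repeat {
    nxt <- reach | (reach %*% adj > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  reach
}

# one-sentence document with annotated mentions given as token ranges
simple_doc <- function(sentences, entities = list(), gold = list(),
                       doc_id = "t") {
  assemble_document(doc_id, sentences, entities, gold)
}

# a multi-sentence document of one-token filler sentences with bacteria
# mentions dropped into chosen sentences (for window-property tests)
layout_doc <- function(bacteria_sents, n_sent) {
  sentences <- lapply(seq_len(n_sent), function(s) {
    if (s %in% bacteria_sents) {
      dplyr::bind_rows(tk("Bacillus", "PROPN", 2, "nsubj"),
                       tk("persisted", "VERB", 0, "root"),
                       tk(".", "PUNCT", 2, "punct"))
    } else {
      dplyr::bind_rows(tk("Results", "NOUN", 2, "nsubj"),
                       tk("followed", "VERB", 0, "root"),
                       tk(".", "PUNCT", 2, "punct"))
    }
  })
  entities <- purrr::imap(sort(bacteria_sents), function(s, i) {
    list(id = paste0("T", i), type = "Bacteria", sentence = s, from = 1,
         to = 1)
  })
  assemble_document("layout", sentences, entities)
}
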