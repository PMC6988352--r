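# Fixture machinery: assembling documents from token tables (used both by
# the packaged worked examples and by the synthetic corpus generator), and
# the seeded template generator that instantiates every syntactic pattern
# and propagation rule with known gold events.

no_space_before <- c(".", ",", ";", ":", ")", "%", "?", "!")
no_space_after <- c("(")

#' Assemble an annotated document from token tables
#'
#' Builds an `annotated_doc` (text, entities, gold events and an attached
#' gold parse) from per-sentence token tibbles. Token offsets are derived
#' from the surfaces: tokens are joined with single spaces except before
#' closing punctuation, after an opening parenthesis, or where `glue` is
#' `TRUE` (the token is appended directly to the previous one, as in
#' hyphenated compounds). Sentences are separated by one space.
#'
#' @param doc_id document identifier.
#' @param sentences list of tibbles with columns `surface`, `upos`, `head`,
#'   `deprel` and optionally `glue` and `lemma`.
#' @param entities list of `list(id, type, sentence, from, to)` token
#'   ranges, or `list(id, type, sentence, tids)` for discontinuous
#'   mentions (`tids` need not be contiguous; each maximal run becomes a
#'   span fragment).
#' @param gold list of `c(bacteria_id, location_id)` pairs.
#' @param equiv list of character vectors of equivalent ids.
#' @return an analyzed `annotated_doc` with `$tokens` and `$alignment`.
#' @export
assemble_document <- function(doc_id, sentences, entities = list(),
                              gold = list(), equiv = list()) {
  toks <- list()
  text <- ""
  for (s in seq_along(sentences)) {
    g <- tibble::as_tibble(sentences[[s]])
    if (!"glue" %in% names(g)) g$glue <- FALSE
    if (!"lemma" %in% names(g)) g$lemma <- tolower(g$surface)
    if (s > 1) text <- paste0(text, " ")
    starts <- ends <- integer(nrow(g))
    for (i in seq_len(nrow(g))) {
      sep <- if (i == 1) "" else if (g$glue[i]) "" else
        if (g$surface[i] %in% no_space_before) "" else
          if (g$surface[i - 1] %in% no_space_after) "" else " "
      text <- paste0(text, sep)
      starts[i] <- nchar(text)
      text <- paste0(text, g$surface[i])
      ends[i] <- nchar(text)
    }
    toks[[s]] <- tibble::tibble(
      sentence = s, tid = seq_len(nrow(g)), surface = g$surface,
      lemma = g$lemma, upos = g$upos, head = as.integer(g$head),
      deprel = g$deprel, start = starts, end = ends
    )
  }
  toks <- dplyr::bind_rows(toks)
  ent_rows <- purrr::map(entities, function(e) {
    tids <- if (!is.null(e$tids)) sort(e$tids) else seq(e$from, e$to)
    st <- toks[toks$sentence == e$sentence & toks$tid %in% tids, ]
    runs <- split(seq_len(nrow(st)), cumsum(c(1, diff(st$tid) != 1)))
    spans <- dplyr::bind_rows(purrr::map(runs, function(r) {
      tibble::tibble(start = min(st$start[r]), end = max(st$end[r]))
    }))
    surface <- paste(purrr::map_chr(seq_len(nrow(spans)), function(k) {
      substr(text, spans$start[k] + 1L, spans$end[k])
    }), collapse = " ")
    tibble::tibble(id = e$id, type = e$type, start = min(spans$start),
                   end = max(spans$end), surface = surface,
                   spans = list(spans))
  })
  ents <- if (length(ent_rows) > 0) dplyr::bind_rows(ent_rows) else
    tibble::tibble(id = character(), type = character(), start = integer(),
                   end = integer(), surface = character(), spans = list())
  gold_events <- if (length(gold) > 0) {
    tibble::tibble(bacteria_id = purrr::map_chr(gold, 1),
                   location_id = purrr::map_chr(gold, 2))
  } else {
    tibble::tibble(bacteria_id = character(), location_id = character())
  }
  doc <- structure(
    list(doc_id = doc_id, text = text, entities = ents, equiv = equiv,
         gold_events = gold_events, tokens = toks),
    class = "annotated_doc"
  )
  doc$alignment <- align_mentions(doc)
  doc
}

#' Write an assembled document as standoff + CoNLL-U files
#'
#' Emits `<doc_id>.txt`, `<doc_id>.a1`, `<doc_id>.a2` (gold events and
#' equivalences) and `<doc_id>.conllu` into `dir`.
#'
#' @param doc an `annotated_doc` with attached tokens.
#' @param dir output directory (created if needed).
#' @return invisibly, the base path `dir/doc_id`.
#' @export
write_standoff <- function(doc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, doc$doc_id)
  writeLines(doc$text, paste0(base, ".txt"), useBytes = TRUE)
  a1 <- purrr::map_chr(seq_len(nrow(doc$entities)), function(i) {
    sp <- doc$entities$spans[[i]]
    offs <- paste(sprintf("%d %d", sp$start, sp$end), collapse = ";")
    sprintf("%s\t%s %s\t%s", doc$entities$id[i], doc$entities$type[i], offs,
            doc$entities$surface[i])
  })
  writeLines(a1, paste0(base, ".a1"), useBytes = TRUE)
  a2 <- character(0)
  if (nrow(doc$gold_events) > 0) {
    a2 <- sprintf("R%d\tLives_In Bacteria:%s Location:%s",
                  seq_len(nrow(doc$gold_events)),
                  doc$gold_events$bacteria_id, doc$gold_events$location_id)
  }
  for (set in doc$equiv) {
    a2 <- c(a2, paste0("*\tEquiv ", paste(set, collapse = " ")))
  }
  writeLines(a2, paste0(base, ".a2"), useBytes = TRUE)
  cl <- character(0)
  for (s in unique(doc$tokens$sentence)) {
    st <- doc$tokens[doc$tokens$sentence == s, ]
    cl <- c(cl, sprintf("%d\t%s\t%s\t%s\t_\t_\t%d\t%s\t_\t_",
                        st$tid, st$surface, st$lemma, st$upos, st$head,
                        st$deprel), "")
  }
  writeLines(cl, paste0(base, ".conllu"), useBytes = TRUE)
  invisible(base)
}

#' Load the packaged worked examples
#'
#' The transcribed worked examples (two-sentence carriage inference;
#' research-goal, negation and if-clause modality cases; coordination,
#' apposition and anaphora cases; the three-sentence screening-culture
#' document) shipped as standoff files with hand-written gold dependency
#' parses. Each comes back analyzed, with its reference events in
#' `gold_events`.
#'
#' @param ids optional character vector of example ids (e.g. `"ex01"`);
#'   default all.
#' @return named list of analyzed `annotated_doc` objects.
#' @export
load_paper_examples <- function(ids = NULL) {
  dir <- system.file("extdata", "examples", package = "triggersieve")
  all_ids <- sort(unique(sub("\\.txt$", "",
                             list.files(dir, pattern = "\\.txt$"))))
  ids <- ids %||% all_ids
  out <- lapply(ids, function(id) {
    doc <- read_document(file.path(dir, paste0(id, ".txt")),
                         file.path(dir, paste0(id, ".a1")),
                         file.path(dir, paste0(id, ".a2")), doc_id = id)
    analyze(doc, backend = "conllu",
            conllu = file.path(dir, paste0(id, ".conllu")))
  })
  stats::setNames(out, ids)
}

# ---------------------------------------------------------------------------
# Synthetic corpus generator

fixture_vocab <- function() {
  list(
    bacteria = c("Helicobacter pylori", "Kingella kingae",
                 "Vibrio salmonicida", "Campylobacter jejuni",
                 "Salmonella enterica", "Pseudomonas aeruginosa"),
    location = c("antrum", "sediments", "patients", "children",
                 "tortoises", "macrophages"),
    trigger = c("elimination", "infection", "colonization", "carriage",
                "bacteremia", "detection")
  )
}

#' Fixture generator configuration
#'
#' @param seed random seed; the same seed yields byte-identical corpora.
#' @param n_docs number of documents to generate.
#' @param template_mix named non-negative weights over the template names
#'   (`P1`, `P2`, `P3`, `N1`, `N2`, `N3`, `R1`..`R5`, `cross_trigger`,
#'   `modality_negative`); default uniform over all.
#' @param vocab word pools (`bacteria`, `location`, `trigger`); defaults to
#'   names printed in the task literature.
#' @return a `fixture_config` list.
#' @export
fixture_config <- function(seed = 1L, n_docs = 10L, template_mix = NULL,
                           vocab = fixture_vocab()) {
  all_templates <- c("P1", "P2", "P3", "N1", "N2", "N3",
                     "R1", "R2", "R3", "R4", "R5",
                     "cross_trigger", "modality_negative")
  if (is.null(template_mix)) {
    template_mix <- stats::setNames(rep(1, length(all_templates)),
                                    all_templates)
  }
  bad <- setdiff(names(template_mix), all_templates)
  if (length(bad) > 0) stop("unknown template(s): ", paste(bad, collapse = ", "),
                            call. = FALSE)
  if (any(template_mix < 0) || sum(template_mix) == 0) {
    stop("template weights must be non-negative and not all zero",
         call. = FALSE)
  }
  for (pool in c("bacteria", "location", "trigger")) {
    if (length(vocab[[pool]]) == 0) {
      stop("empty vocabulary pool: ", pool, call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), n_docs = as.integer(n_docs),
                 template_mix = template_mix, vocab = vocab),
            class = "fixture_config")
}

tok <- function(surface, upos, head, deprel, glue = FALSE) {
  tibble::tibble(surface = surface, upos = upos, head = as.integer(head),
                 deprel = deprel, glue = glue)
}

# bacteria-name token rows: first token heads the mention, rest attach flat
bacteria_tokens <- function(name, head, deprel, offset) {
  parts <- strsplit(name, " ")[[1]]
  dplyr::bind_rows(
    tok(parts[1], "PROPN", head, deprel),
    if (length(parts) > 1) {
      dplyr::bind_rows(lapply(parts[-1], function(p) {
        tok(p, "PROPN", offset, "flat")
      }))
    }
  )
}

# each template returns list(sentences, entities, gold); token heads are
# written against the final within-sentence numbering
fixture_templates <- function() {
  list(
    # "The {T} of {B} in the {L} was reported ."
    P1 = function(b, l, tr) {
      nb <- length(strsplit(b, " ")[[1]])
      s <- dplyr::bind_rows(
        tok("The", "DET", 2, "det"),
        tok(tr, "NOUN", 6 + nb, "nsubj:pass"),
        tok("of", "ADP", 4, "case"),
        bacteria_tokens(b, 2, "nmod", 4),
        tok("in", "ADP", 7 + nb - 1, "case"),
        tok("the", "DET", 7 + nb - 1, "det"),
        tok(l, "NOUN", 2, "nmod"),
        tok("was", "AUX", 6 + nb, "aux:pass"),
        tok("reported", "VERB", 0, "root"),
        tok(".", "PUNCT", 6 + nb, "punct")
      )
      # positions: 1 The, 2 T, 3 of, 4..(3+nb) B, 4+nb in, 5+nb the,
      # 6+nb-? recompute: l at 6+nb, was 7+nb, reported 8+nb, . 9+nb
      s$head <- c(2L, 8L + nb, 4L, 2L, rep(4L, nb - 1), 6L + nb, 6L + nb,
                  2L, 8L + nb, 0L, 8L + nb)[seq_len(nrow(s))]
      list(sentences = list(s),
           entities = list(list(id = "T1", type = "Bacteria", sentence = 1,
                                from = 4, to = 3 + nb),
                           list(id = "T2", type = "Habitat", sentence = 1,
                                from = 6 + nb, to = 6 + nb)),
           gold = list(c("T1", "T2")))
    },
    # "{B} {T} in the {L} was reported ."
    P2 = function(b, l, tr) {
      nb <- length(strsplit(b, " ")[[1]])
      s <- dplyr::bind_rows(
        bacteria_tokens(b, 1 + nb, "compound", 1),
        tok(tr, "NOUN", 6 + nb, "nsubj:pass"),
        tok("in", "ADP", 4 + nb, "case"),
        tok("the", "DET", 4 + nb, "det"),
        tok(l, "NOUN", 1 + nb, "nmod"),
        tok("was", "AUX", 6 + nb, "aux:pass"),
        tok("reported", "VERB", 0, "root"),
        tok(".", "PUNCT", 6 + nb, "punct")
      )
      list(sentences = list(s),
           entities = list(list(id = "T1", type = "Bacteria", sentence = 1,
                                from = 1, to = nb),
                           list(id = "T2", type = "Habitat", sentence = 1,
                                from = 4 + nb, to = 4 + nb)),
           gold = list(c("T1", "T2")))
    },
    # "{L} {T} of {B} increased ."
    P3 = function(b, l, tr) {
      nb <- length(strsplit(b, " ")[[1]])
      s <- dplyr::bind_rows(
        tok(l, "NOUN", 2, "compound"),
        tok(tr, "NOUN", 4 + nb, "nsubj"),
        tok("of", "ADP", 4, "case"),
        bacteria_tokens(b, 2, "nmod", 4),
        tok("increased", "VERB", 0, "root"),
        tok(".", "PUNCT", 4 + nb, "punct")
      )
      list(sentences = list(s),
           entities = list(list(id = "T1", type = "Bacteria", sentence = 1,
                                from = 4, to = 3 + nb),
                           list(id = "T2", type = "Habitat", sentence = 1,
                                from = 1, to = 1)),
           gold = list(c("T1", "T2")))
    },
    # "The {L} pathogen {B} was detected ."
    N1 = function(b, l, tr) {
      nb <- length(strsplit(b, " ")[[1]])
      s <- dplyr::bind_rows(
        tok("The", "DET", 3, "det"),
        tok(l, "NOUN", 3, "compound"),
        tok("pathogen", "NOUN", 5 + nb, "nsubj:pass"),
        bacteria_tokens(b, 3, "appos", 4),
        tok("was", "AUX", 5 + nb, "aux:pass"),
        tok("detected", "VERB", 0, "root"),
        tok(".", "PUNCT", 5 + nb, "punct")
      )
      list(sentences = list(s),
           entities = list(list(id = "T1", type = "Bacteria", sentence = 1,
                                from = 4, to = 3 + nb),
                           list(id = "T2", type = "Habitat", sentence = 1,
                                from = 2, to = 2)),
           gold = list(c("T1", "T2")))
    },
    # "Samples of {B}-infected {L} were examined daily ." (B nested in L)
    N2 = function(b, l, tr) {
      nb <- length(strsplit(b, " ")[[1]])
      s <- dplyr::bind_rows(
        tok("Samples", "NOUN", 6 + nb, "nsubj:pass"),
        tok("of", "ADP", 4 + nb, "case"),
        bacteria_tokens(b, 3 + nb, "compound", 3),
        tok("-infected", "VERB", 4 + nb, "acl", glue = TRUE),
        tok(l, "NOUN", 1, "nmod"),
        tok("were", "AUX", 6 + nb, "aux:pass"),
        tok("collected", "VERB", 0, "root"),
        tok(".", "PUNCT", 6 + nb, "punct")
      )
      list(sentences = list(s),
           entities = list(list(id = "T1", type = "Bacteria", sentence = 1,
                                from = 3, to = 2 + nb),
                           list(id = "T2", type = "Habitat", sentence = 1,
                                from = 3, to = 4 + nb)),
           gold = list(c("T1", "T2")))
    },
    # "Resistance appeared in {B} in the {L} ."
    N3 = function(b, l, tr) {
      nb <- length(strsplit(b, " ")[[1]])
      s <- dplyr::bind_rows(
        tok("Resistance", "NOUN", 2, "nsubj"),
        tok("appeared", "VERB", 0, "root"),
        tok("in", "ADP", 4, "case"),
        bacteria_tokens(b, 2, "obl", 4),
        tok("in", "ADP", 6 + nb, "case"),
        tok("the", "DET", 6 + nb, "det"),
        tok(l, "NOUN", 4, "nmod"),
        tok(".", "PUNCT", 2, "punct")
      )
      list(sentences = list(s),
           entities = list(list(id = "T1", type = "Bacteria", sentence = 1,
                                from = 4, to = 3 + nb),
                           list(id = "T2", type = "Habitat", sentence = 1,
                                from = 6 + nb, to = 6 + nb)),
           gold = list(c("T1", "T2")))
    },
    # "{B} was found in apple and lettuce surfaces ." (nested mentions,
    # one discontinuous)
    R1 = function(b, l, tr) {
      nb <- length(strsplit(b, " ")[[1]])
      ap <- 4 + nb; le <- 6 + nb; su <- 7 + nb
      s <- dplyr::bind_rows(
        bacteria_tokens(b, 2 + nb, "nsubj:pass", 1),
        tok("was", "AUX", 2 + nb, "aux:pass"),
        tok("found", "VERB", 0, "root"),
        tok("in", "ADP", su, "case"),
        tok("apple", "NOUN", su, "compound"),
        tok("and", "CCONJ", le, "cc"),
        tok("lettuce", "NOUN", ap, "conj"),
        tok("surfaces", "NOUN", 2 + nb, "obl"),
        tok(".", "PUNCT", 2 + nb, "punct")
      )
      list(sentences = list(s),
           entities = list(
             list(id = "T1", type = "Bacteria", sentence = 1, from = 1, to = nb),
             list(id = "T2", type = "Habitat", sentence = 1, from = ap, to = su),
             list(id = "T3", type = "Habitat", sentence = 1, tids = c(ap, su)),
             list(id = "T4", type = "Habitat", sentence = 1, from = le, to = su),
             list(id = "T5", type = "Habitat", sentence = 1, from = ap, to = ap),
             list(id = "T6", type = "Habitat", sentence = 1, from = le, to = le)),
           gold = list(c("T1", "T2"), c("T1", "T3"), c("T1", "T4"),
                       c("T1", "T5"), c("T1", "T6")))
    },
    # "{B} {T} in tryptic soy broth and nutrient broth was reported ."
    R2 = function(b, l, tr) {
      nb <- length(strsplit(b, " ")[[1]])
      t1 <- 1 + nb; br1 <- 5 + nb; br2 <- 8 + nb; rp <- 10 + nb
      s <- dplyr::bind_rows(
        bacteria_tokens(b, t1, "compound", 1),
        tok(tr, "NOUN", rp, "nsubj:pass"),
        tok("in", "ADP", br1, "case"),
        tok("tryptic", "ADJ", br1, "amod"),
        tok("soy", "NOUN", br1, "compound"),
        tok("broth", "NOUN", t1, "nmod"),
        tok("and", "CCONJ", br2, "cc"),
        tok("nutrient", "NOUN", br2, "compound"),
        tok("broth", "NOUN", br1, "conj"),
        tok("was", "AUX", rp, "aux:pass"),
        tok("reported", "VERB", 0, "root"),
        tok(".", "PUNCT", rp, "punct")
      )
      list(sentences = list(s),
           entities = list(
             list(id = "T1", type = "Bacteria", sentence = 1, from = 1, to = nb),
             list(id = "T2", type = "Habitat", sentence = 1, from = 3 + nb, to = br1),
             list(id = "T3", type = "Habitat", sentence = 1, from = 7 + nb, to = br2)),
           gold = list(c("T1", "T2"), c("T1", "T3")))
    },
    # "{B} ( XY ) {T} in a skilled nursing facility ( SNF ) was reported ."
    R3 = function(b, l, tr) {
      nb <- length(strsplit(b, " ")[[1]])
      abbr <- toupper(paste(substr(strsplit(b, " ")[[1]], 1, 1),
                            collapse = ""))
      ab <- 2 + nb; t1 <- 4 + nb; fa <- 9 + nb; sn <- 11 + nb
      rp <- 14 + nb
      s <- dplyr::bind_rows(
        bacteria_tokens(b, t1, "compound", 1),
        tok("(", "PUNCT", ab, "punct"),
        tok(abbr, "PROPN", 1, "appos"),
        tok(")", "PUNCT", ab, "punct"),
        tok(tr, "NOUN", rp, "nsubj:pass"),
        tok("in", "ADP", fa, "case"),
        tok("a", "DET", fa, "det"),
        tok("skilled", "ADJ", fa, "amod"),
        tok("nursing", "NOUN", fa, "compound"),
        tok("facility", "NOUN", t1, "nmod"),
        tok("(", "PUNCT", sn, "punct"),
        tok("SNF", "PROPN", fa, "appos"),
        tok(")", "PUNCT", sn, "punct"),
        tok("was", "AUX", rp, "aux:pass"),
        tok("reported", "VERB", 0, "root"),
        tok(".", "PUNCT", rp, "punct")
      )
      list(sentences = list(s),
           entities = list(
             list(id = "T1", type = "Bacteria", sentence = 1, from = 1, to = nb),
             list(id = "T2", type = "Bacteria", sentence = 1, from = ab, to = ab),
             list(id = "T3", type = "Habitat", sentence = 1, from = 6 + nb, to = fa),
             list(id = "T4", type = "Habitat", sentence = 1, from = sn, to = sn)),
           gold = list(c("T1", "T3"), c("T2", "T3"), c("T1", "T4"),
                       c("T2", "T4")))
    },
    # "{B} {T} in Georgia , USA was reported ."
    R4 = function(b, l, tr) {
      nb <- length(strsplit(b, " ")[[1]])
      t1 <- 1 + nb; ge <- 3 + nb; us <- 5 + nb
      s <- dplyr::bind_rows(
        bacteria_tokens(b, t1, "compound", 1),
        tok(tr, "NOUN", 7 + nb, "nsubj:pass"),
        tok("in", "ADP", ge, "case"),
        tok("Georgia", "PROPN", t1, "nmod"),
        tok(",", "PUNCT", us, "punct"),
        tok("USA", "PROPN", ge, "dep"),
        tok("was", "AUX", 7 + nb, "aux:pass"),
        tok("reported", "VERB", 0, "root"),
        tok(".", "PUNCT", 7 + nb, "punct")
      )
      list(sentences = list(s),
           entities = list(
             list(id = "T1", type = "Bacteria", sentence = 1, from = 1, to = nb),
             list(id = "T2", type = "Geographical", sentence = 1, from = ge, to = ge),
             list(id = "T3", type = "Geographical", sentence = 1, from = us, to = us)),
           gold = list(c("T1", "T2"), c("T1", "T3")))
    },
    # "{B} {T} in travelers returning from Nepal was reported ."
    R5 = function(b, l, tr) {
      nb <- length(strsplit(b, " ")[[1]])
      t1 <- 1 + nb; tv <- 3 + nb; rt <- 4 + nb; np <- 6 + nb
      s <- dplyr::bind_rows(
        bacteria_tokens(b, t1, "compound", 1),
        tok(tr, "NOUN", 8 + nb, "nsubj:pass"),
        tok("in", "ADP", tv, "case"),
        tok("travelers", "NOUN", t1, "nmod"),
        tok("returning", "VERB", tv, "acl"),
        tok("from", "ADP", np, "case"),
        tok("Nepal", "PROPN", rt, "obl"),
        tok("was", "AUX", 8 + nb, "aux:pass"),
        tok("reported", "VERB", 0, "root"),
        tok(".", "PUNCT", 8 + nb, "punct")
      )
      list(sentences = list(s),
           entities = list(
             list(id = "T1", type = "Bacteria", sentence = 1, from = 1, to = nb),
             list(id = "T2", type = "Habitat", sentence = 1, from = tv, to = tv),
             list(id = "T3", type = "Geographical", sentence = 1, from = np, to = np)),
           gold = list(c("T1", "T2"), c("T1", "T3")))
    },
    # S1: "{B} caused severe illness ."  S2: "The {T} in the {L} was high ."
    cross_trigger = function(b, l, tr) {
      nb <- length(strsplit(b, " ")[[1]])
      s1 <- dplyr::bind_rows(
        bacteria_tokens(b, 1 + nb, "nsubj", 1),
        tok("caused", "VERB", 0, "root"),
        tok("severe", "ADJ", 3 + nb, "amod"),
        tok("illness", "NOUN", 1 + nb, "obj"),
        tok(".", "PUNCT", 1 + nb, "punct")
      )
      s2 <- dplyr::bind_rows(
        tok("The", "DET", 2, "det"),
        tok(tr, "NOUN", 8, "nsubj"),
        tok("in", "ADP", 5, "case"),
        tok("the", "DET", 5, "det"),
        tok(l, "NOUN", 2, "nmod"),
        tok("was", "AUX", 8, "cop"),
        tok("notably", "ADV", 8, "advmod"),
        tok("high", "ADJ", 0, "root"),
        tok(".", "PUNCT", 8, "punct")
      )
      list(sentences = list(s1, s2),
           entities = list(
             list(id = "T1", type = "Bacteria", sentence = 1, from = 1, to = nb),
             list(id = "T2", type = "Habitat", sentence = 2, from = 5, to = 5)),
           gold = list(c("T1", "T2")))
    },
    # "To evaluate the {T} of {B} in the {L} , samples were collected ."
    modality_negative = function(b, l, tr) {
      nb <- length(strsplit(b, " ")[[1]])
      lt <- 8 + nb
      s <- dplyr::bind_rows(
        tok("To", "PART", 2, "mark"),
        tok("evaluate", "VERB", 12 + nb, "advcl"),
        tok("the", "DET", 4, "det"),
        tok(tr, "NOUN", 2, "obj"),
        tok("of", "ADP", 6, "case"),
        bacteria_tokens(b, 4, "nmod", 6),
        tok("in", "ADP", lt, "case"),
        tok("the", "DET", lt, "det"),
        tok(l, "NOUN", 4, "nmod"),
        tok(",", "PUNCT", 12 + nb, "punct"),
        tok("samples", "NOUN", 12 + nb, "nsubj:pass"),
        tok("were", "AUX", 12 + nb, "aux:pass"),
        tok("collected", "VERB", 0, "root"),
        tok(".", "PUNCT", 12 + nb, "punct")
      )
      list(sentences = list(s),
           entities = list(
             list(id = "T1", type = "Bacteria", sentence = 1, from = 6, to = 5 + nb),
             list(id = "T2", type = "Habitat", sentence = 1, from = lt, to = lt)),
           gold = list())
    }
  )
}

#' Generate a seeded synthetic corpus
#'
#' Builds documents from sentence templates that instantiate the named
#' syntactic pattern or propagation rule with pool words; the gold events
#' of each document are exactly those the template entails. Templates are
#' rule-coverage instruments, not realistic discourse: no document places
#' two bacteria mentions in one sentence unless the template requires it.
#' The same seed yields byte-identical output.
#'
#' @param cfg a [fixture_config()].
#' @return list of analyzed `annotated_doc` objects (gold events set,
#'   template recorded in `$template`).
#' @export
generate_corpus <- function(cfg = fixture_config()) {
  stopifnot(inherits(cfg, "fixture_config"))
  templates <- fixture_templates()
  mix <- cfg$template_mix[cfg$template_mix > 0]
  old_seed <- if (exists(".Random.seed", envir = .GlobalEnv,
                         inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  })
  set.seed(cfg$seed)
  out <- vector("list", cfg$n_docs)
  for (i in seq_len(cfg$n_docs)) {
    tname <- sample(names(mix), 1, prob = mix)
    b <- sample(cfg$vocab$bacteria, 1)
    l <- sample(cfg$vocab$location, 1)
    tr <- sample(cfg$vocab$trigger, 1)
    spec <- templates[[tname]](b, l, tr)
    doc <- assemble_document(sprintf("synth-%03d-%s", i, tname),
                             spec$sentences, spec$entities, spec$gold)
    doc$template <- tname
    out[[i]] <- doc
  }
  out
}
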