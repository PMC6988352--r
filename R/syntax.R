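#' Tokens, dependency trees and mention alignment
#'
#' Every sieve in the pipeline consumes one flat tokens tibble per document
#' with columns `sentence` (1-based sentence index), `tid` (1-based token
#' index within its sentence), `surface`, `lemma`, `upos` (UD coarse tag),
#' `head` (`tid` of the governor, 0 for the root), `deprel` (UD relation),
#' and `start`/`end` (0-based half-open character offsets into the document
#' text). Two backends produce this layer: `"conllu"` reads a gold parse in
#' CoNLL-U format, `"heuristic"` runs a small deterministic
#' tokenizer/tagger/attacher adequate for simple declarative sentences
#' (its limits are described in the package vignette).
#'
#' Entity mentions that would cross a predicted sentence boundary force the
#' two sentences to be merged so no mention is ever split.
#'
#' @param doc an `annotated_doc` from [read_document()].
#' @param backend `"conllu"` or `"heuristic"`.
#' @param conllu path to, or character lines of, a CoNLL-U gold parse
#'   (required for the `"conllu"` backend unless `doc$tokens` is already
#'   set).
#' @return the document with `$tokens` and `$alignment` filled in;
#'   `$alignment` is a tibble `id`, `sentence`, `head_tid`, `tids`
#'   (list-column) mapping each entity mention to its sentence, its
#'   syntactic head token and its covered tokens.
#' @export
analyze <- function(doc, backend = c("conllu", "heuristic"), conllu = NULL) {
  backend <- match.arg(backend)
  if (!nzchar(doc$text)) stop("document text is empty", call. = FALSE)
  if (backend == "conllu") {
    if (is.null(conllu) && is.null(doc$tokens)) {
      stop("conllu backend requires a gold parse", call. = FALSE)
    }
    toks <- if (!is.null(conllu)) read_conllu(conllu, doc$text) else doc$tokens
  } else {
    toks <- heuristic_parse(doc$text)
  }
  toks <- merge_split_mentions(toks, doc$entities)
  doc$tokens <- toks
  doc$alignment <- align_mentions(doc)
  doc
}

#' Read a CoNLL-U parse and align it to document text
#'
#' Standard 10-column CoNLL-U; multiword-token and empty-node lines are
#' skipped. Character offsets are recovered by matching each token's surface
#' form left-to-right in the text.
#'
#' @param x file path or character vector of CoNLL-U lines.
#' @param text the document text the parse belongs to.
#' @return a tokens tibble (see [analyze()]).
#' @export
read_conllu <- function(x, text) {
  lines <- if (length(x) == 1 && file.exists(x)) {
    readLines(x, warn = FALSE, encoding = "UTF-8")
  } else x
  lines <- lines[!grepl("^#", lines)]
  sent <- 1L
  rows <- list()
  blank_run <- TRUE
  for (ln in lines) {
    if (!nzchar(trimws(ln))) {
      if (!blank_run) sent <- sent + 1L
      blank_run <- TRUE
      next
    }
    blank_run <- FALSE
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) stop("malformed CoNLL-U line: ", ln, call. = FALSE)
    if (grepl("[-.]", f[[1]])) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      sentence = sent, tid = as.integer(f[[1]]), surface = f[[2]],
      lemma = if (f[[3]] == "_") tolower(f[[2]]) else f[[3]],
      upos = f[[4]], head = as.integer(f[[7]]), deprel = f[[8]]
    )
  }
  toks <- dplyr::bind_rows(rows)
  if (nrow(toks) == 0) stop("empty CoNLL-U input", call. = FALSE)
  offset_align(toks, text)
}

# locate each token's character offsets by greedy left-to-right matching
offset_align <- function(toks, text) {
  cursor <- 0L
  starts <- ends <- integer(nrow(toks))
  for (i in seq_len(nrow(toks))) {
    surf <- toks$surface[[i]]
    pos <- regexpr(surf, substr(text, cursor + 1L, nchar(text)), fixed = TRUE)
    if (pos < 0) {
      stop(sprintf("token '%s' not found in text after offset %d", surf, cursor),
           call. = FALSE)
    }
    starts[i] <- cursor + as.integer(pos) - 1L
    ends[i] <- starts[i] + nchar(surf)
    cursor <- ends[i]
  }
  toks$start <- starts
  toks$end <- ends
  toks
}

# ---------------------------------------------------------------------------
# Heuristic backend: regex tokenizer, lexicon/suffix POS tagger, and a
# deterministic dependency attacher for simple declarative sentences.

closed_class <- list(
  det = c("the", "a", "an", "this", "that", "these", "those", "no", "none",
          "any", "some", "each", "every", "both", "all"),
  adp = c("in", "on", "to", "from", "at", "of", "with", "by", "for", "among",
          "within", "into", "onto", "between", "during", "under", "over",
          "after", "before", "through", "via", "as"),
  cconj = c("and", "or", "but"),
  sconj = c("if", "whether", "because", "although", "while", "that", "when"),
  aux = c("is", "are", "was", "were", "be", "been", "being", "could",
          "would", "should", "can", "may", "might", "must", "will", "has",
          "have", "had", "do", "does", "did"),
  pron = c("it", "they", "we", "he", "she", "its", "their", "our", "which",
           "who", "them")
)

tag_word <- function(w, prev_tag) {
  lw <- tolower(w)
  if (grepl("^[[:punct:]]+$", w)) return("PUNCT")
  if (grepl("^[0-9.%]+$", w)) return("NUM")
  if (lw %in% closed_class$det) return("DET")
  if (lw %in% closed_class$cconj) return("CCONJ")
  if (lw %in% closed_class$sconj) return("SCONJ")
  if (lw %in% closed_class$aux) return("AUX")
  if (lw %in% closed_class$pron) return("PRON")
  if (lw %in% closed_class$adp) return("ADP")
  if (grepl("(ed|ing)$", lw) && nchar(lw) > 4) return("VERB")
  if (grepl("(al|ic|ous|ive|ary|like)$", lw) && nchar(lw) > 4) return("ADJ")
  if (grepl("(tion|sion|ment|ness|ance|ence|ity|age|ure|ism)s?$", lw)) return("NOUN")
  if (grepl("s$", lw) && prev_tag %in% c("DET", "ADJ", "ADP", "NOUN")) return("NOUN")
  "NOUN"
}

tokenize_text <- function(text) {
  m <- gregexpr("[A-Za-z0-9]+(?:[-'.][A-Za-z0-9]+)*|[^A-Za-z0-9[:space:]]",
                text)[[1]]
  if (m[1] < 0) return(tibble::tibble(surface = character(), start = integer(),
                                      end = integer()))
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  tibble::tibble(
    surface = substring(text, starts + 1L, starts + lens),
    start = starts, end = starts + lens
  )
}

heuristic_parse <- function(text) {
  raw <- tokenize_text(text)
  if (nrow(raw) == 0) stop("no tokens in text", call. = FALSE)
  # sentence split after ./!/? when followed by an upper-case or digit token;
  # internal abbreviation dots survive because they stay inside word tokens
  sent <- integer(nrow(raw))
  s <- 1L
  for (i in seq_len(nrow(raw))) {
    sent[i] <- s
    if (raw$surface[i] %in% c(".", "!", "?") && i < nrow(raw) &&
        grepl("^[A-Z0-9]", raw$surface[i + 1])) {
      s <- s + 1L
    }
  }
  raw$sentence <- sent
  out <- raw |>
    dplyr::group_by(.data$sentence) |>
    dplyr::group_map(function(g, key) {
      g$tid <- seq_len(nrow(g))
      prev <- "NONE"
      tags <- character(nrow(g))
      for (i in seq_len(nrow(g))) {
        tags[i] <- tag_word(g$surface[i], prev)
        prev <- tags[i]
      }
      # first AUX followed by VERB keeps VERB as predicate; lone AUX is copula
      g$upos <- tags
      g$lemma <- tolower(g$surface)
      attach_heads(g, key$sentence)
    }) |>
    dplyr::bind_rows()
  out[, c("sentence", "tid", "surface", "lemma", "upos", "head", "deprel",
          "start", "end")]
}

# simple right-branching attachment for NP (det/amod/compound) + PP chains
attach_heads <- function(g, sent_idx) {
  n <- nrow(g)
  g$sentence <- sent_idx
  g$head <- 0L
  g$deprel <- "dep"
  upos <- g$upos
  # nominal runs: maximal stretches of DET/ADJ/NOUN/NUM/PROPN; head = last noun
  nominal <- upos %in% c("DET", "ADJ", "NOUN", "NUM")
  run_id <- integer(n); rid <- 0L
  for (i in seq_len(n)) {
    if (nominal[i]) {
      if (i == 1 || !nominal[i - 1]) rid <- rid + 1L
      run_id[i] <- rid
    }
  }
  np_head <- integer(0)
  for (r in seq_len(max(run_id, 0))) {
    ids <- which(run_id == r)
    nouns <- ids[upos[ids] %in% c("NOUN", "NUM")]
    h <- if (length(nouns) > 0) max(nouns) else max(ids)
    np_head[r] <- h
    for (i in ids) {
      if (i == h) next
      g$head[i] <- h
      g$deprel[i] <- switch(upos[i], DET = "det", ADJ = "amod", NUM = "nummod",
                            "compound")
    }
  }
  verbs <- which(upos == "VERB")
  root <- if (length(verbs) > 0) verbs[[1]] else if (length(np_head) > 0)
    np_head[[1]] else 1L
  g$head[root] <- 0L
  g$deprel[root] <- "root"
  prev_head_stack <- root
  # attach NP heads, prepositions, verbs, conjunctions
  last_nominal_head <- 0L
  for (i in seq_len(n)) {
    if (i == root) { if (nominal[i]) last_nominal_head <- i; next }
    if (nominal[i] && np_head[run_id[i]] == i) {
      # NP head: subject if before root verb, else object/oblique
      prev_adp <- 0L
      j <- i - 1L
      while (j > 0 && g$head[j] == i) j <- j - 1L   # skip own modifiers
      if (j > 0 && upos[j] == "ADP") prev_adp <- j
      if (prev_adp > 0) {
        g$head[prev_adp] <- i
        g$deprel[prev_adp] <- "case"
        att <- if (last_nominal_head > 0) last_nominal_head else root
        g$head[i] <- att
        g$deprel[i] <- if (upos[att] == "VERB") "obl" else "nmod"
      } else if (j > 0 && upos[j] == "CCONJ" && last_nominal_head > 0) {
        g$head[j] <- i
        g$deprel[j] <- "cc"
        g$head[i] <- last_nominal_head
        g$deprel[i] <- "conj"
      } else if (i < root || length(which(upos == "VERB")) == 0) {
        g$head[i] <- root
        g$deprel[i] <- "nsubj"
      } else {
        g$head[i] <- root
        g$deprel[i] <- "obj"
      }
      last_nominal_head <- i
    } else if (upos[i] == "VERB" && i != root) {
      if (i > 1 && upos[i - 1] %in% c("NOUN", "NUM")) {
        g$head[i] <- last_nominal_head
        g$deprel[i] <- "acl"
      } else {
        g$head[i] <- root
        g$deprel[i] <- "conj"
      }
    } else if (upos[i] == "AUX") {
      g$head[i] <- root
      g$deprel[i] <- if (length(verbs) > 0) "aux" else "cop"
    } else if (upos[i] == "SCONJ") {
      nxt_v <- verbs[verbs > i]
      g$head[i] <- if (length(nxt_v) > 0) nxt_v[[1]] else root
      g$deprel[i] <- "mark"
    } else if (upos[i] == "PUNCT") {
      g$head[i] <- root
      g$deprel[i] <- "punct"
    } else if (g$head[i] == 0L) {
      g$head[i] <- root
      g$deprel[i] <- "dep"
    }
  }
  g
}

# merge sentences whenever an entity span crosses a sentence boundary
merge_split_mentions <- function(toks, entities) {
  if (nrow(entities) == 0) return(toks)
  repeat {
    bad <- NULL
    for (i in seq_len(nrow(entities))) {
      sp <- entities$spans[[i]]
      cov <- unique(toks$sentence[purrr::map_lgl(
        seq_len(nrow(toks)),
        function(j) any(toks$start[j] < sp$end & toks$end[j] > sp$start)
      )])
      if (length(cov) > 1) { bad <- sort(cov)[1:2]; break }
    }
    if (is.null(bad)) break
    toks <- merge_sentences(toks, bad[1], bad[2])
  }
  toks
}

merge_sentences <- function(toks, s1, s2) {
  n1 <- sum(toks$sentence == s1)
  i2 <- toks$sentence == s2
  root2 <- which(i2 & toks$head == 0L)
  toks$head[i2] <- ifelse(toks$head[i2] == 0L, 0L, toks$head[i2] + n1)
  toks$tid[i2] <- toks$tid[i2] + n1
  toks$sentence[i2] <- s1
  # second root becomes parataxis under the first root
  root1 <- which(toks$sentence == s1 & toks$head == 0L & toks$deprel == "root")[1]
  i2w <- which(toks$sentence == s1 & toks$tid > n1 & toks$head == 0L)
  if (length(i2w) > 0) {
    toks$head[i2w] <- toks$tid[root1]
    toks$deprel[i2w] <- "parataxis"
  }
  toks$sentence[toks$sentence > s2] <- toks$sentence[toks$sentence > s2] - 1L
  toks
}

# ---------------------------------------------------------------------------
# Mention alignment and tree predicates

align_mentions <- function(doc) {
  toks <- doc$tokens
  ents <- doc$entities
  if (nrow(ents) == 0) {
    return(tibble::tibble(id = character(), sentence = integer(),
                          head_tid = integer(), tids = list()))
  }
  purrr::map_dfr(seq_len(nrow(ents)), function(i) {
    sp <- ents$spans[[i]]
    hit <- purrr::map_lgl(seq_len(nrow(toks)), function(j) {
      any(toks$start[j] < sp$end & toks$end[j] > sp$start)
    })
    sents <- unique(toks$sentence[hit])
    if (length(sents) != 1) {
      stop(sprintf("mention %s aligns to %d sentences", ents$id[i],
                   length(sents)), call. = FALSE)
    }
    sent_toks <- toks[toks$sentence == sents, ]
    tids <- toks$tid[hit]
    head_tid <- mention_head(sent_toks, tids)
    tibble::tibble(id = ents$id[i], sentence = sents, head_tid = head_tid,
                   tids = list(tids))
  })
}

# the token inside the mention whose governor lies outside it (fallback: last)
mention_head <- function(sent_toks, tids) {
  inside <- sent_toks$tid %in% tids
  heads <- sent_toks$head[inside]
  ext <- sent_toks$tid[inside][!(heads %in% tids)]
  if (length(ext) > 0) ext[[length(ext)]] else max(tids)
}

sentence_tokens <- function(toks, s) toks[toks$sentence == s, ]

#' Is one token a proper dependency descendant of another?
#'
#' @param sent tokens tibble of a single sentence.
#' @param node,ancestor token `tid`s within the sentence.
#' @return `TRUE` iff `ancestor` lies on the head path from `node` to the
#'   root (proper dominance: a token is not its own descendant).
#' @export
is_descendant <- function(sent, node, ancestor) {
  h <- sent$head[match(node, sent$tid)]
  steps <- 0L
  while (!is.na(h) && h != 0L && steps <= nrow(sent)) {
    if (h == ancestor) return(TRUE)
    h <- sent$head[match(h, sent$tid)]
    steps <- steps + 1L
  }
  FALSE
}

descendants_of <- function(sent, ancestor) {
  sent$tid[purrr::map_lgl(sent$tid, ~ is_descendant(sent, .x, ancestor))]
}

clause_boundary_rels <- c("ccomp", "xcomp", "advcl", "acl", "acl:relcl",
                         "csubj", "csubj:pass", "parataxis")

# deprel labels on the dependency path between a and b
path_rels <- function(sent, a, b) {
  chain <- function(x) {
    out <- x
    h <- sent$head[match(x, sent$tid)]
    while (!is.na(h) && h != 0L) {
      out <- c(out, h)
      h <- sent$head[match(h, sent$tid)]
    }
    out
  }
  ca <- chain(a); cb <- chain(b)
  lca <- intersect(ca, cb)[1]
  up <- function(ch) {
    if (is.na(lca)) ch else ch[seq_len(match(lca, ch) - 1L)]
  }
  nodes <- c(up(ca), up(cb))
  sent$deprel[match(nodes, sent$tid)]
}

#' Do two tokens belong to the same clause?
#'
#' True iff the dependency path between the tokens crosses no
#' clause-boundary relation (`ccomp`, `xcomp`, `advcl`, `acl`, `acl:relcl`,
#' `csubj`, `parataxis`, or `conj` between two verbs).
#'
#' @param sent tokens tibble of a single sentence.
#' @param a,b token `tid`s.
#' @return logical.
#' @export
same_clause <- function(sent, a, b) {
  if (a == b) return(TRUE)
  rels_on_path <- path_rels(sent, a, b)
  if (any(rels_on_path %in% clause_boundary_rels)) return(FALSE)
  # conj between verbs counts as a clause boundary
  if (any(rels_on_path == "conj")) {
    conj_nodes <- sent$tid[sent$deprel == "conj" & sent$upos == "VERB"]
    # recompute the path nodes to see whether a verbal conj edge is crossed
    for (cn in conj_nodes) {
      on_a <- cn == a || is_descendant(sent, a, cn)
      on_b <- cn == b || is_descendant(sent, b, cn)
      if (xor(on_a, on_b)) return(FALSE)
    }
  }
  TRUE
}

#' Token and sentence distance between two mentions
#'
#' @param doc an analyzed `annotated_doc`.
#' @param id_a,id_b entity ids, or trigger positions given as
#'   `list(sentence =, tids =)`.
#' @return a list with `words` (tokens strictly between the two mentions in
#'   document order) and `sentences` (absolute sentence-index difference).
#' @export
word_distance <- function(doc, id_a, id_b) {
  loc <- function(x) {
    if (is.character(x)) {
      al <- doc$alignment[doc$alignment$id == x, ]
      if (nrow(al) == 0) stop("unaligned mention: ", x, call. = FALSE)
      list(sentence = al$sentence, tids = al$tids[[1]])
    } else x
  }
  a <- loc(id_a); b <- loc(id_b)
  ord <- doc$tokens
  gpos <- function(m) which(ord$sentence == m$sentence & ord$tid %in% m$tids)
  pa <- gpos(a); pb <- gpos(b)
  if (min(pa) > min(pb)) { tmp <- pa; pa <- pb; pb <- tmp }
  between <- max(0L, min(pb) - max(pa) - 1L)
  list(words = between, sentences = abs(a$sentence - b$sentence))
}
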