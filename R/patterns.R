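# Dependency patterns shared by trigger mining and intra-clause event
# extraction. An "anchor" fills the bacteria slot and is either a bacteria
# mention (head token + covered tokens) or a single trigger token.
#
# Trigger patterns (noun slot underlined is what mining collects):
#   P1  {noun} of [bacteria] loc_prep [location]
#   P2  [bacteria] {n/v/p} loc_prep [location]
#   P3  [location] {n/v/p} prep [bacteria]
# Additional intra-clause event patterns:
#   N1  bacteria and location nested in one noun phrase
#   N2  one mention's span nested inside the other's
#   N3  a direct prepositional edge between the two mention heads

#' Locational prepositions
#'
#' The five prepositions used to constrain the location slot of the trigger
#' patterns. `extended = TRUE` appends within/into/onto (the published list
#' is open-ended; the default is the five listed forms).
#'
#' @param extended include within/into/onto.
#' @return character vector of lower-case prepositions.
#' @export
locational_prepositions <- function(extended = FALSE) {
  base <- c("in", "on", "to", "from", "at")
  if (extended) c(base, "within", "into", "onto") else base
}

tok_row <- function(sent, tid) match(tid, sent$tid)

children_of <- function(sent, tid, rels = NULL) {
  k <- sent$head == tid
  if (!is.null(rels)) k <- k & sent$deprel %in% rels
  sent$tid[k]
}

# lemma of the ADP/SCONJ case or mark child of a token ("" if none)
case_of <- function(sent, tid) {
  kids <- children_of(sent, tid, c("case", "mark"))
  kids <- kids[sent$upos[match(kids, sent$tid)] %in% c("ADP", "SCONJ")]
  if (length(kids) == 0) return("")
  sent$lemma[tok_row(sent, min(kids))]
}

nominal_rels <- c("compound", "nmod", "amod", "nsubj", "nsubj:pass", "obl",
                  "obj", "appos", "flat")
np_cluster_rels <- c("compound", "amod", "flat", "appos", "nummod", "fixed")

# connected components of the NP-internal relation graph
np_clusters <- function(sent) {
  comp <- sent$tid
  edges <- which(sent$deprel %in% np_cluster_rels & sent$head != 0L)
  repeat {
    changed <- FALSE
    for (i in edges) {
      a <- comp[i]
      b <- comp[tok_row(sent, sent$head[i])]
      if (a != b) {
        comp[comp == max(a, b)] <- min(a, b)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# prepositional dependents of `tid`: nmod/obl children carrying a case word
prep_dependents <- function(sent, tid, preps = NULL) {
  kids <- children_of(sent, tid, c("nmod", "obl"))
  keep <- purrr::map_lgl(kids, function(k) {
    cs <- case_of(sent, k)
    nzchar(cs) && (is.null(preps) || cs %in% preps)
  })
  kids[keep]
}

# does `gov` govern `dep` through a preposition in `preps`
prep_edge <- function(sent, gov, dep, preps = NULL) {
  dep %in% prep_dependents(sent, gov, preps)
}

#' Match the trigger patterns in one sentence
#'
#' Finds tokens filling the noun/verb/participle slot of the three trigger
#' patterns relative to a bacteria-slot anchor. With
#' `require_location = FALSE` (unlabeled-corpus mining) the location slot is
#' unconstrained and only the preposition is checked; with
#' `require_location = TRUE` the location slot must be the head of one of
#' `location_heads`, and the matched (trigger token, location head) pairs
#' are returned.
#'
#' @param sent tokens tibble of one sentence.
#' @param anchor_head `tid` of the bacteria-slot head token.
#' @param anchor_tids all `tid`s covered by the anchor.
#' @param location_heads `tid`s of candidate location mention heads
#'   (required when `require_location = TRUE`).
#' @param require_location constrain the location slot to annotated mentions.
#' @param loc_preps locational prepositions (see
#'   [locational_prepositions()]).
#' @param exclude_tids token ids that may not fill the trigger slot (e.g.
#'   tokens inside annotated entities).
#' @return tibble `pattern`, `trigger_tid`, `location_head` (`NA` in mining
#'   mode).
#' @export
match_trigger_patterns <- function(sent, anchor_head, anchor_tids,
                                   location_heads = integer(0),
                                   require_location = FALSE,
                                   loc_preps = locational_prepositions(),
                                   exclude_tids = integer(0)) {
  out <- list()
  add <- function(pattern, trig, loc) {
    out[[length(out) + 1L]] <<- tibble::tibble(
      pattern = pattern, trigger_tid = trig, location_head = loc
    )
  }
  slot_ok <- function(tid) {
    !(tid %in% anchor_tids) && !(tid %in% exclude_tids) &&
      sent$upos[tok_row(sent, tid)] %in% c("NOUN", "VERB", "ADJ")
  }
  loc_sites <- function(gov, preps) {
    # location attachment on `gov` or on the anchor head
    hits <- c(prep_dependents(sent, gov, preps),
              prep_dependents(sent, anchor_head, preps))
    hits <- setdiff(unique(hits), c(anchor_tids, gov))
    if (require_location) intersect(hits, location_heads) else hits
  }

  # P1: {noun} of [bacteria] loc_prep [location]
  gov_h <- sent$head[tok_row(sent, anchor_head)]
  if (!is.na(gov_h) && gov_h != 0L &&
      sent$deprel[tok_row(sent, anchor_head)] %in% c("nmod", "obl") &&
      case_of(sent, anchor_head) == "of" &&
      sent$upos[tok_row(sent, gov_h)] == "NOUN" && slot_ok(gov_h)) {
    for (l in loc_sites(gov_h, loc_preps)) add("P1", gov_h, l)
    if (!require_location && length(loc_sites(gov_h, loc_preps)) == 0) {
      # nothing: P1 needs the locational phrase
    }
  }

  # P2: [bacteria] {n/v/p} loc_prep [location]
  p2_slots <- integer(0)
  if (!is.na(gov_h) && gov_h != 0L &&
      sent$deprel[tok_row(sent, anchor_head)] %in%
        c("compound", "nmod", "amod", "nsubj", "nsubj:pass", "flat") &&
      case_of(sent, anchor_head) != "of") {
    p2_slots <- c(p2_slots, gov_h)
  }
  p2_slots <- c(p2_slots,
                children_of(sent, anchor_head, c("acl", "acl:relcl")))
  for (x in unique(p2_slots)) {
    if (!slot_ok(x)) next
    for (l in loc_sites(x, loc_preps)) add("P2", x, l)
  }

  # P3: [location] {n/v/p} prep [bacteria]  (any preposition)
  if (!is.na(gov_h) && gov_h != 0L &&
      sent$deprel[tok_row(sent, anchor_head)] %in% c("nmod", "obl") &&
      nzchar(case_of(sent, anchor_head)) && slot_ok(gov_h)) {
    x <- gov_h
    if (require_location) {
      mods <- children_of(sent, x, c("amod", "compound"))
      for (l in intersect(mods, location_heads)) add("P3", x, l)
    } else {
      add("P3", x, NA_integer_)
    }
  }

  if (length(out) == 0) {
    return(tibble::tibble(pattern = character(), trigger_tid = integer(),
                          location_head = integer()))
  }
  dplyr::distinct(dplyr::bind_rows(out))
}

# N-pattern matches between an anchor and location mention heads.
# Returns tibble(pattern, location_head).
match_nested_patterns <- function(sent, anchor_head, anchor_tids,
                                  location_heads,
                                  loc_preps = locational_prepositions()) {
  out <- list()
  add <- function(p, l) {
    out[[length(out) + 1L]] <<- tibble::tibble(pattern = p, location_head = l)
  }
  comp <- np_clusters(sent)
  for (l in setdiff(location_heads, anchor_tids)) {
    # N1: same noun-phrase cluster
    if (comp[tok_row(sent, l)] == comp[tok_row(sent, anchor_head)]) {
      add("N1", l)
    }
    # N3: direct prepositional edge, either direction, any preposition
    if (prep_edge(sent, anchor_head, l) || prep_edge(sent, l, anchor_head)) {
      add("N3", l)
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(pattern = character(), location_head = integer()))
  }
  dplyr::distinct(dplyr::bind_rows(out))
}
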