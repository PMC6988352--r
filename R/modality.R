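# Hypothesis / research-goal / conditional / negation filtering. Mentions
# and triggers falling inside such scopes are removed before any inference
# consumes them; filtering is purely subtractive.

# hypothesis keywords: the research-purpose non-trigger class plus verb forms
modality_keywords <- function() {
  c("determine", "determination", "evaluate", "evaluation", "study",
    "analysis", "analyze", "examination", "examine", "assess", "assessment",
    "investigate", "investigation", "inspect", "inspection")
}

negation_words <- c("not", "no", "none")

#' Find tokens blocked by linguistic modality
#'
#' Blocks (a) all dependency descendants of a hypothesis keyword
#' (determine, evaluate, study, analysis, ...), (b) all tokens inside
#' if-clauses or whether-clauses, and (c) tokens of mentions directly
#' modified by not/no/none-of, or governed by a predicate negated via not.
#'
#' @param doc an analyzed `annotated_doc`.
#' @param keywords hypothesis keyword lemmas (defaults to the packaged
#'   list).
#' @param negations negation lemmas (default not/no/none).
#' @return tibble `sentence`, `tid`, `reason` with reason one of
#'   `"hypothesis-keyword"`, `"if-whether-clause"`, `"negation"`.
#' @export
find_blocked_tokens <- function(doc, keywords = modality_keywords(),
                                negations = negation_words) {
  stopifnot(!is.null(doc$tokens))
  out <- list()
  add <- function(s, tids, reason) {
    if (length(tids) > 0) {
      out[[length(out) + 1L]] <<- tibble::tibble(sentence = s, tid = tids,
                                                 reason = reason)
    }
  }
  # exact lower-cased surface match: the keyword list enumerates both the
  # nominal and the verbal forms, so inflected variants (e.g. "studied")
  # deliberately do not block
  for (s in unique(doc$tokens$sentence)) {
    sent <- sentence_tokens(doc$tokens, s)
    # (a) descendants of hypothesis keywords
    kw_tids <- sent$tid[tolower(sent$surface) %in% keywords]
    for (k in kw_tids) add(s, descendants_of(sent, k), "hypothesis-keyword")
    # (b) if-/whether-clauses: subtrees of heads carrying such a mark
    marks <- sent$tid[sent$deprel == "mark" & sent$lemma %in% c("if", "whether")]
    for (m in marks) {
      h <- sent$head[tok_row(sent, m)]
      if (h == 0L) next
      add(s, c(h, descendants_of(sent, h)), "if-whether-clause")
    }
    # (c) negation: direct det/advmod negation or "none of X"
    neg_tids <- sent$tid[sent$lemma %in% negations]
    for (ng in neg_tids) {
      r <- tok_row(sent, ng)
      h <- sent$head[r]
      if (sent$lemma[r] %in% c("no", "not") && h != 0L &&
          sent$deprel[r] %in% c("det", "advmod")) {
        hr <- tok_row(sent, h)
        if (sent$upos[hr] %in% c("NOUN", "PROPN", "NUM", "PRON")) {
          add(s, h, "negation")                     # negated nominal
        } else if (sent$upos[hr] %in% c("VERB", "ADJ", "AUX")) {
          # mentions governed by a negated predicate
          add(s, children_of(sent, h, c("nsubj", "nsubj:pass", "obj", "obl",
                                        "nmod")), "negation")
        }
      }
      # "none of X": X attaches to "none" via a prepositional edge
      if (sent$lemma[r] == "none") {
        add(s, prep_dependents(sent, ng, "of"), "negation")
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(sentence = integer(), tid = integer(),
                          reason = character()))
  }
  dplyr::distinct(dplyr::bind_rows(out), .data$sentence, .data$tid,
                  .keep_all = TRUE)
}

#' Apply the modality filter
#'
#' A mention or trigger is removed iff its head token is blocked. Other
#' mentions in the same sentence remain eligible.
#'
#' @param doc an analyzed `annotated_doc`.
#' @param triggers detected trigger tibble.
#' @param blocked output of [find_blocked_tokens()].
#' @return list with `blocked_ids` (entity ids to exclude) and `triggers`
#'   (the retained trigger rows).
#' @export
apply_modality_filter <- function(doc, triggers, blocked) {
  key <- paste(blocked$sentence, blocked$tid)
  al <- doc$alignment
  blocked_ids <- al$id[paste(al$sentence, al$head_tid) %in% key]
  keep <- !(paste(triggers$sentence, triggers$tid) %in% key)
  list(blocked_ids = blocked_ids, triggers = triggers[keep, ])
}
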