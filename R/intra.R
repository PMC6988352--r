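# Intra-sentence sieves: intra-clause pattern extraction, trigger linking,
# cross-clause inference by trigger transitivity, and event-label
# propagation to a fixpoint.

empty_events <- function() {
  tibble::tibble(bacteria_id = character(), location_id = character(),
                 provenance = character())
}

add_events <- function(events, bacteria_id, location_id, provenance) {
  if (length(bacteria_id) == 0) return(events)
  dplyr::bind_rows(events, tibble::tibble(
    bacteria_id = bacteria_id, location_id = location_id,
    provenance = provenance
  ))
}

# duplicates collapse to one event keeping the earliest provenance
dedupe_events <- function(events) {
  dplyr::distinct(events, .data$bacteria_id, .data$location_id,
                  .keep_all = TRUE)
}

alignment_of <- function(doc, id) {
  al <- doc$alignment[doc$alignment$id == id, ]
  if (nrow(al) == 0) stop("unaligned mention: ", id, call. = FALSE)
  al
}

# character-span containment between two mentions (proper or equal extent
# with distinct ids)
span_nested <- function(doc, inner, outer) {
  e <- doc$entities
  i <- match(inner, e$id); o <- match(outer, e$id)
  e$start[i] >= e$start[o] && e$end[i] <= e$end[o] && inner != outer
}

#' Extract intra-clause events
#'
#' Applies the trigger patterns P1-P3 (with the location slot required to be
#' an annotated Habitat/Geographical mention) and the three nested patterns:
#' N1 (bacteria and location inside one noun phrase), N2 (one mention's span
#' nested inside the other's) and N3 (a direct prepositional edge between
#' the two mention heads), for every bacteria mention. Mentions listed in
#' `blocked_ids` (modality filtering) are excluded as either participant.
#'
#' @param doc an analyzed `annotated_doc`.
#' @param blocked_ids entity ids removed by the modality filter.
#' @param loc_preps locational prepositions for P1/P2.
#' @return events tibble `bacteria_id`, `location_id`, `provenance`.
#' @export
extract_intra_clause <- function(doc, blocked_ids = character(0),
                                 loc_preps = locational_prepositions()) {
  events <- empty_events()
  al <- doc$alignment
  bids <- setdiff(bacteria_ids(doc), blocked_ids)
  lids <- setdiff(location_ids(doc), blocked_ids)
  if (length(bids) == 0 || length(lids) == 0) return(events)
  for (bid in bids) {
    ba <- alignment_of(doc, bid)
    sent <- sentence_tokens(doc$tokens, ba$sentence)
    co_loc <- al[al$id %in% lids & al$sentence == ba$sentence, ]
    if (nrow(co_loc) == 0) next
    head2id <- stats::setNames(co_loc$id, co_loc$head_tid)
    m <- match_trigger_patterns(sent, ba$head_tid, ba$tids[[1]],
                                location_heads = co_loc$head_tid,
                                require_location = TRUE,
                                loc_preps = loc_preps)
    nm <- match_nested_patterns(sent, ba$head_tid, ba$tids[[1]],
                                co_loc$head_tid, loc_preps)
    hits <- dplyr::bind_rows(
      m[, c("pattern", "location_head")],
      nm
    )
    for (k in seq_len(nrow(hits))) {
      lid <- unname(head2id[as.character(hits$location_head[k])])
      if (is.na(lid)) next
      if (!same_clause(sent, ba$head_tid,
                       co_loc$head_tid[match(lid, co_loc$id)])) next
      events <- add_events(events, bid, lid, paste0("intra:", hits$pattern[k]))
    }
    # N2: nesting between the two mentions themselves
    for (lid in co_loc$id) {
      if (span_nested(doc, bid, lid) || span_nested(doc, lid, bid)) {
        events <- add_events(events, bid, lid, "intra:N2")
      }
    }
  }
  dedupe_events(events)
}

#' Link triggers to their nearest bacteria mention
#'
#' Each trigger is linked to the bacteria mention closest to it. Within a
#' sentence (`scope = "intra"`) closeness is the number of words between
#' them; across sentences (`scope = "cross"`) the primary key is sentence
#' distance and the secondary key word distance. Ties go to the preceding
#' mention.
#'
#' @param doc an analyzed `annotated_doc`.
#' @param triggers tibble from [detect_triggers()].
#' @param scope `"intra"` restricts candidates to the trigger's sentence;
#'   `"cross"` considers all bacteria mentions in the document.
#' @param bacteria_ids_use optional subset of linkable bacteria ids.
#' @return `triggers` with a `linked_bacteria` column (`NA` when no
#'   candidate exists).
#' @export
link_triggers <- function(doc, triggers, scope = c("intra", "cross"),
                          bacteria_ids_use = NULL) {
  scope <- match.arg(scope)
  bids <- bacteria_ids_use %||% bacteria_ids(doc)
  triggers$linked_bacteria <- NA_character_
  if (nrow(triggers) == 0 || length(bids) == 0) return(triggers)
  bal <- doc$alignment[doc$alignment$id %in% bids, ]
  for (i in seq_len(nrow(triggers))) {
    tpos <- list(sentence = triggers$sentence[i], tids = triggers$tid[i])
    cand <- if (scope == "intra") {
      bal[bal$sentence == triggers$sentence[i], ]
    } else bal
    if (nrow(cand) == 0) next
    d <- purrr::map(cand$id, ~ word_distance(doc, tpos, .x))
    sd <- purrr::map_int(d, ~ as.integer(.x$sentences))
    wd <- purrr::map_int(d, ~ as.integer(.x$words))
    # preceding mentions win ties (reading order)
    precedes <- purrr::map_lgl(seq_len(nrow(cand)), function(k) {
      a <- cand[k, ]
      a$sentence < tpos$sentence ||
        (a$sentence == tpos$sentence && max(a$tids[[1]]) < tpos$tids[1])
    })
    ord <- order(sd, wd, !precedes)
    triggers$linked_bacteria[i] <- cand$id[ord[1]]
  }
  triggers
}

# trigger -> location intra-clause links, the trigger token standing in the
# bacteria slot; returns tibble(sentence, tid, location_id, pattern)
trigger_location_links <- function(doc, triggers,
                                   blocked_ids = character(0),
                                   loc_preps = locational_prepositions()) {
  out <- tibble::tibble(sentence = integer(), tid = integer(),
                        location_id = character(), pattern = character())
  lids <- setdiff(location_ids(doc), blocked_ids)
  if (nrow(triggers) == 0 || length(lids) == 0) return(out)
  lal <- doc$alignment[doc$alignment$id %in% lids, ]
  for (i in seq_len(nrow(triggers))) {
    s <- triggers$sentence[i]
    sent <- sentence_tokens(doc$tokens, s)
    co_loc <- lal[lal$sentence == s, ]
    if (nrow(co_loc) == 0) next
    head2id <- stats::setNames(co_loc$id, co_loc$head_tid)
    tt <- triggers$tid[i]
    m <- match_trigger_patterns(sent, tt, tt,
                                location_heads = co_loc$head_tid,
                                require_location = TRUE,
                                loc_preps = loc_preps)
    nm <- match_nested_patterns(sent, tt, tt, co_loc$head_tid, loc_preps)
    hits <- dplyr::bind_rows(m[, c("pattern", "location_head")], nm)
    for (k in seq_len(nrow(hits))) {
      lh <- hits$location_head[k]
      if (!same_clause(sent, tt, lh)) next
      out <- dplyr::bind_rows(out, tibble::tibble(
        sentence = s, tid = tt,
        location_id = unname(head2id[as.character(lh)]),
        pattern = hits$pattern[k]
      ))
    }
  }
  dplyr::distinct(out)
}

#' Infer cross-clause events by trigger transitivity
#'
#' For each trigger already linked to a bacteria mention within its
#' sentence, every location the trigger reaches through an intra-clause
#' pattern (the trigger standing in the bacteria slot) yields an event
#' between the linked bacteria and that location.
#'
#' @param doc an analyzed `annotated_doc`.
#' @param linked_triggers output of [link_triggers()] with scope "intra".
#' @param intra_events events already extracted (for deduplication).
#' @param blocked_ids entity ids removed by the modality filter.
#' @param loc_preps locational prepositions.
#' @return events tibble including the inputs plus the inferred events.
#' @export
infer_cross_clause <- function(doc, linked_triggers,
                               intra_events = empty_events(),
                               blocked_ids = character(0),
                               loc_preps = locational_prepositions()) {
  lt <- linked_triggers[!is.na(linked_triggers$linked_bacteria), ]
  if (nrow(lt) == 0) return(dedupe_events(intra_events))
  links <- trigger_location_links(doc, lt, blocked_ids, loc_preps)
  events <- intra_events
  for (k in seq_len(nrow(links))) {
    b <- lt$linked_bacteria[lt$sentence == links$sentence[k] &
                              lt$tid == links$tid[k]][1]
    events <- add_events(events, b, links$location_id[k],
                         paste0("cross_clause:", links$pattern[k]))
  }
  dedupe_events(events)
}

# ---------------------------------------------------------------------------
# Propagation (five syntactic relations between same-type mentions)

# all directed propagation relations in the document:
# tibble(from, to, rule); an event on `from` extends to `to`
propagation_relations <- function(doc) {
  e <- doc$entities
  al <- doc$alignment
  out <- list()
  add <- function(from, to, rule) {
    out[[length(out) + 1L]] <<- tibble::tibble(from = from, to = to, rule = rule)
  }
  same_type <- function(i, j) {
    (e$type[i] == "Bacteria") == (e$type[j] == "Bacteria")
  }
  gap_text <- function(i, j) substr(doc$text, e$end[i] + 1L, e$start[j])
  n <- nrow(e)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || !same_type(i, j)) next
      ai <- al[al$id == e$id[i], ]; aj <- al[al$id == e$id[j], ]
      if (ai$sentence != aj$sentence) next
      sent <- sentence_tokens(doc$tokens, ai$sentence)
      hi <- ai$head_tid; hj <- aj$head_tid
      # R1 nesting (both directions; emitted once per ordered pair)
      if (span_nested(doc, e$id[j], e$id[i]) ||
          span_nested(doc, e$id[i], e$id[j])) {
        add(e$id[i], e$id[j], "R1")
      }
      # R2 coordination of same-type mentions
      if ((sent$head[tok_row(sent, hj)] == hi &&
           sent$deprel[tok_row(sent, hj)] == "conj") ||
          (sent$head[tok_row(sent, hi)] == hj &&
           sent$deprel[tok_row(sent, hi)] == "conj")) {
        add(e$id[i], e$id[j], "R2")
      }
      # R3 apposition, incl. parenthesized abbreviation right after a mention
      appos <- (sent$head[tok_row(sent, hj)] == hi &&
                  sent$deprel[tok_row(sent, hj)] == "appos") ||
        (sent$head[tok_row(sent, hi)] == hj &&
           sent$deprel[tok_row(sent, hi)] == "appos")
      paren <- (e$start[j] > e$end[i] &&
                  grepl("^\\s*\\($", gap_text(i, j))) ||
        (e$start[i] > e$end[j] &&
           grepl("^\\s*\\($", gap_text(j, i)))
      if (appos || paren) add(e$id[i], e$id[j], "R3")
      # R4 comma-joined geographical hierarchy: smaller (first) -> larger
      if (e$type[i] == "Geographical" && e$type[j] == "Geographical" &&
          e$start[j] > e$end[i] && grepl("^\\s*,\\s*$", gap_text(i, j))) {
        add(e$id[i], e$id[j], "R4")
      }
      # R5 participle-preposition / single preposition: governor -> object
      participles <- children_of(sent, hi, c("acl", "acl:relcl"))
      r5 <- prep_edge(sent, hi, hj) ||
        any(purrr::map_lgl(participles, ~ prep_edge(sent, .x, hj)))
      if (r5) add(e$id[i], e$id[j], "R5")
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(from = character(), to = character(),
                          rule = character()))
  }
  dplyr::distinct(dplyr::bind_rows(out))
}

#' Propagate event labels to a fixpoint
#'
#' Extends the input event set through the five propagation relations
#' between same-type mention pairs — R1 nesting, R2 coordination, R3
#' apposition (including parenthesized abbreviations), R4 comma-joined
#' geographical hierarchy (smaller region to larger) and R5
#' participle-preposition / single-preposition linking — applied on both
#' the bacteria and the location side, repeatedly, until no new pair is
#' identified. The result is the smallest closed superset of the input;
#' re-applying [propagate()] is a no-op.
#'
#' @param doc an analyzed `annotated_doc`.
#' @param events events tibble.
#' @param relations optionally precomputed [propagation_relations()]
#'   (internal use).
#' @param blocked_ids entity ids the closure may not introduce.
#' @return the closed events tibble; added events carry provenance
#'   `prop:<rule>`.
#' @export
propagate <- function(doc, events, relations = NULL,
                      blocked_ids = character(0)) {
  if (nrow(events) == 0) return(events)
  rel <- relations %||% propagation_relations(doc)
  if (length(blocked_ids) > 0) {
    rel <- rel[!(rel$to %in% blocked_ids), ]
  }
  if (nrow(rel) == 0) return(dedupe_events(events))
  btype <- stats::setNames(doc$entities$type == "Bacteria", doc$entities$id)
  events <- dedupe_events(events)
  repeat {
    key <- paste(events$bacteria_id, events$location_id)
    new <- list()
    for (k in seq_len(nrow(rel))) {
      f <- rel$from[k]; t <- rel$to[k]
      if (btype[[f]]) {
        hit <- events$bacteria_id == f
        cand_b <- rep(t, sum(hit)); cand_l <- events$location_id[hit]
      } else {
        hit <- events$location_id == f
        cand_b <- events$bacteria_id[hit]; cand_l <- rep(t, sum(hit))
      }
      if (length(cand_b) == 0) next
      fresh <- !(paste(cand_b, cand_l) %in% key)
      if (any(fresh)) {
        new[[length(new) + 1L]] <- tibble::tibble(
          bacteria_id = cand_b[fresh], location_id = cand_l[fresh],
          provenance = paste0("prop:", rel$rule[k])
        )
      }
    }
    if (length(new) == 0) break
    events <- dedupe_events(dplyr::bind_rows(events, dplyr::bind_rows(new)))
    if (nrow(events) > nrow(doc$entities)^2) break  # safety bound
  }
  events
}
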