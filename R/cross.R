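# Cross-sentence sieve: candidate selection, bacteria-anchored context
# windows, and trigger-transitive inference across sentence boundaries.

#' Select candidate mentions for cross-sentence events
#'
#' A bacteria mention is a candidate iff its sentence contains no location
#' mention at all, or it already has at least one intra-sentence event. A
#' location mention is a candidate iff it has no intra-sentence event (a
#' location with an intra-sentence relation never takes a cross-sentence
#' one).
#'
#' @param doc an analyzed `annotated_doc`.
#' @param intra_events intra-sentence events tibble.
#' @return list with `bacteria` and `locations` character vectors of ids.
#' @export
select_candidates <- function(doc, intra_events) {
  al <- doc$alignment
  lids <- location_ids(doc)
  bids <- bacteria_ids(doc)
  loc_sents <- al$sentence[al$id %in% lids]
  bac_ok <- purrr::map_lgl(bids, function(b) {
    s <- al$sentence[al$id == b]
    !any(loc_sents == s) || b %in% intra_events$bacteria_id
  })
  loc_ok <- !(lids %in% intra_events$location_id)
  list(bacteria = bids[bac_ok], locations = lids[loc_ok])
}

#' Build the context window of a bacteria mention
#'
#' The maximal sentence range within `size` sentences either side of the
#' anchor, truncated before any sentence containing another bacteria
#' mention and clipped to the document. When a second bacteria mention
#' shares the anchor's sentence no window exists and `NULL` is returned.
#'
#' @param doc an analyzed `annotated_doc`.
#' @param bacteria_id the anchor bacteria mention id.
#' @param size window half-width in sentences (default 3).
#' @return list `bacteria_id`, `lo`, `hi` (inclusive sentence range), or
#'   `NULL`.
#' @export
build_window <- function(doc, bacteria_id, size = 3L) {
  al <- doc$alignment
  s <- al$sentence[al$id == bacteria_id]
  if (length(s) == 0) stop("unaligned mention: ", bacteria_id, call. = FALSE)
  other_bac_sents <- al$sentence[al$id %in% setdiff(bacteria_ids(doc),
                                                    bacteria_id)]
  if (any(other_bac_sents == s)) return(NULL)
  n_sent <- max(doc$tokens$sentence)
  lo <- s
  while (lo - 1L >= max(1L, s - size) && !any(other_bac_sents == lo - 1L)) {
    lo <- lo - 1L
  }
  hi <- s
  while (hi + 1L <= min(n_sent, s + size) && !any(other_bac_sents == hi + 1L)) {
    hi <- hi + 1L
  }
  list(bacteria_id = bacteria_id, lo = lo, hi = hi)
}

#' Infer cross-sentence events
#'
#' For each candidate bacteria mention in document order, triggers inside
#' its context window (outside its own sentence) whose globally nearest
#' bacteria mention is the anchor act as its indirect anaphors; every
#' candidate location such a trigger reaches through an intra-clause
#' pattern yields a cross-sentence event. The propagation closure then runs
#' over the combined event set, restricted so that no cross-sentence event
#' acquires a location that already has an intra-sentence event.
#'
#' @param doc an analyzed `annotated_doc`.
#' @param triggers detected triggers ([detect_triggers()]), already
#'   modality-filtered.
#' @param intra_events intra-sentence events tibble.
#' @param window_size context window half-width (default 3 sentences).
#' @param blocked_ids entity ids removed by the modality filter.
#' @param loc_preps locational prepositions.
#' @return the combined events tibble (intra + cross + propagation).
#' @export
infer_cross_sentence <- function(doc, triggers, intra_events,
                                 window_size = 3L,
                                 blocked_ids = character(0),
                                 loc_preps = locational_prepositions()) {
  cand <- select_candidates(doc, intra_events)
  cand$bacteria <- setdiff(cand$bacteria, blocked_ids)
  cand$locations <- setdiff(cand$locations, blocked_ids)
  events <- dedupe_events(intra_events)
  if (length(cand$bacteria) == 0 || length(cand$locations) == 0 ||
      nrow(triggers) == 0) {
    return(events)
  }
  linked <- link_triggers(doc, triggers, scope = "cross",
                          bacteria_ids_use = setdiff(bacteria_ids(doc),
                                                     blocked_ids))
  links <- trigger_location_links(doc, triggers, blocked_ids, loc_preps)
  al <- doc$alignment
  # document order: by mention start offset
  ord <- order(doc$entities$start[match(cand$bacteria, doc$entities$id)])
  cross <- empty_events()
  for (b in cand$bacteria[ord]) {
    win <- build_window(doc, b, window_size)
    if (is.null(win)) next
    bs <- al$sentence[al$id == b]
    in_win <- linked$sentence >= win$lo & linked$sentence <= win$hi &
      linked$sentence != bs & linked$linked_bacteria == b &
      !is.na(linked$linked_bacteria)
    if (!any(in_win)) next
    for (i in which(in_win)) {
      hit <- links[links$sentence == linked$sentence[i] &
                     links$tid == linked$tid[i], ]
      for (k in seq_len(nrow(hit))) {
        lid <- hit$location_id[k]
        if (!(lid %in% cand$locations)) next
        lsent <- al$sentence[al$id == lid]
        if (lsent < win$lo || lsent > win$hi) next
        cross <- add_events(cross, b, lid,
                            paste0("cross_sentence:", hit$pattern[k]))
      }
    }
  }
  combined <- propagate(doc, dedupe_events(dplyr::bind_rows(events, cross)),
                        blocked_ids = blocked_ids)
  # a location with an intra-sentence event never takes a cross-sentence
  # one; events already present on input (e.g. supplied externally) are
  # never dropped
  input_keys <- paste(events$bacteria_id, events$location_id)
  drop <- purrr::map_lgl(seq_len(nrow(combined)), function(i) {
    key <- paste(combined$bacteria_id[i], combined$location_id[i])
    if (key %in% input_keys) return(FALSE)
    bsent <- al$sentence[al$id == combined$bacteria_id[i]]
    lsent <- al$sentence[al$id == combined$location_id[i]]
    bsent != lsent && !(combined$location_id[i] %in% cand$locations)
  })
  combined[!drop, ]
}
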