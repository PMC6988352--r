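#' Matching-similarity evaluation
#'
#' Scores predicted Lives_In events against reference events using the
#' shared task's matching similarity: a predicted pair is correct iff some
#' reference pair has the same (or Equiv-declared equivalent) bacteria id
#' and the same (or equivalent) location id. Precision, recall and F1 are
#' reported overall and split by intra- versus cross-sentence events.
#'
#' @name evaluation
NULL

# canonical representative of an id under the Equiv partition
equiv_canon <- function(ids, equiv) {
  vapply(ids, function(x) {
    for (set in equiv) if (x %in% set) return(sort(set)[1])
    x
  }, character(1))
}

#' Count correct predicted events
#'
#' @param predicted,reference tibbles with `bacteria_id`, `location_id`.
#' @param equiv list of character vectors of mutually equivalent ids.
#' @param known_ids optional vector of valid entity ids; any other id is an
#'   error.
#' @return number of deduplicated predicted pairs matching some reference
#'   pair.
#' @export
match_events <- function(predicted, reference, equiv = list(),
                         known_ids = NULL) {
  if (!is.null(known_ids)) {
    bad <- setdiff(c(predicted$bacteria_id, predicted$location_id,
                     reference$bacteria_id, reference$location_id), known_ids)
    if (length(bad) > 0) {
      stop("dangling entity id(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  pkey <- unique(paste(equiv_canon(predicted$bacteria_id, equiv),
                       equiv_canon(predicted$location_id, equiv)))
  rkey <- unique(paste(equiv_canon(reference$bacteria_id, equiv),
                       equiv_canon(reference$location_id, equiv)))
  sum(pkey %in% rkey)
}

# round half up at one decimal (reproduces the published rounding, e.g.
# 58.15 -> 58.2)
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Precision, recall and F1 from count triples
#'
#' `P = 100 * correct / predicted`, `R = 100 * correct / gold`,
#' `F1 = 2PR/(P+R)`, each defined as 0 when its denominator is 0. F1 is
#' computed from the unrounded precision and recall; all three are reported
#' rounded half-up at one decimal.
#'
#' @param gold,predicted,correct non-negative counts with
#'   `correct <= min(gold, predicted)`.
#' @return tibble `gold`, `predicted`, `correct`, `precision`, `recall`,
#'   `f1` (percentages).
#' @export
prf <- function(gold, predicted, correct) {
  if (any(c(gold, predicted, correct) < 0) ||
      correct > min(gold, predicted)) {
    stop("invalid counts: need 0 <= correct <= min(gold, predicted)",
         call. = FALSE)
  }
  p <- if (predicted > 0) 100 * correct / predicted else 0
  r <- if (gold > 0) 100 * correct / gold else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  tibble::tibble(gold = gold, predicted = predicted, correct = correct,
                 precision = round_half_up(p), recall = round_half_up(r),
                 f1 = round_half_up(f))
}

#' Split events into intra- and cross-sentence strata
#'
#' @param doc an analyzed `annotated_doc`.
#' @param events events tibble.
#' @return `events` with a `sentence_span` column (`"intra"` or
#'   `"cross"`).
#' @export
stratify_events <- function(doc, events) {
  al <- doc$alignment
  events$sentence_span <- purrr::map_chr(seq_len(nrow(events)), function(i) {
    bs <- al$sentence[al$id == events$bacteria_id[i]]
    ls <- al$sentence[al$id == events$location_id[i]]
    if (length(bs) == 0 || length(ls) == 0) {
      stop("dangling entity id in events", call. = FALSE)
    }
    if (bs == ls) "intra" else "cross"
  })
  events
}

#' Evaluate predictions over one or more documents
#'
#' @param docs an analyzed `annotated_doc` or list of them (each carrying
#'   `gold_events`).
#' @param predictions an events tibble, or a list parallel to `docs`.
#' @return an `eval_report`: tibble with rows `intra`, `cross`, `all` and
#'   columns `stratum`, `gold`, `predicted`, `correct`, `precision`,
#'   `recall`, `f1`.
#' @export
evaluate_events <- function(docs, predictions) {
  if (inherits(docs, "annotated_doc")) {
    docs <- list(docs)
    predictions <- list(predictions)
  }
  counts <- list(intra = c(0, 0, 0), cross = c(0, 0, 0))
  for (i in seq_along(docs)) {
    doc <- docs[[i]]
    pred <- dedupe_events(predictions[[i]])
    gold <- stratify_events(doc, dplyr::distinct(doc$gold_events))
    pred <- stratify_events(doc, pred)
    for (st in c("intra", "cross")) {
      g <- gold[gold$sentence_span == st, ]
      p <- pred[pred$sentence_span == st, ]
      counts[[st]] <- counts[[st]] + c(
        nrow(g), nrow(p),
        match_events(p, g, doc$equiv, known_ids = doc$entities$id)
      )
    }
  }
  all3 <- counts$intra + counts$cross
  rows <- dplyr::bind_rows(
    dplyr::mutate(prf(counts$intra[1], counts$intra[2], counts$intra[3]),
                  stratum = "intra", .before = 1),
    dplyr::mutate(prf(counts$cross[1], counts$cross[2], counts$cross[3]),
                  stratum = "cross", .before = 1),
    dplyr::mutate(prf(all3[1], all3[2], all3[3]), stratum = "all", .before = 1)
  )
  structure(rows, class = c("eval_report", class(rows)))
}
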