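#' Pipeline configuration
#'
#' @param lexicon a trigger lexicon tibble, or `"train"`/`"unlabeled"` to
#'   load a packaged one, or `NULL` for no trigger-based inference (mode
#'   M1).
#' @param window_size context-window half-width in sentences (default 3).
#' @param modality apply hypothesis/negation/research-goal filtering.
#' @param external_intra optional externally predicted intra-sentence
#'   events: an events tibble or a path to an `.a2` file (modes M4/M5);
#'   when supplied it replaces the rule-based intra-sentence output.
#' @param backend parser backend passed to [analyze()].
#' @param extended_preps use the extended locational-preposition list.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(lexicon = "unlabeled", window_size = 3L,
                            modality = TRUE, external_intra = NULL,
                            backend = "conllu", extended_preps = FALSE) {
  if (is.character(lexicon) && length(lexicon) == 1) {
    lexicon <- load_packaged_lexicon(lexicon)
  }
  if (window_size < 0) stop("window size must be >= 0", call. = FALSE)
  structure(list(lexicon = lexicon, window_size = as.integer(window_size),
                 modality = isTRUE(modality), external_intra = external_intra,
                 backend = backend,
                 loc_preps = locational_prepositions(extended_preps)),
            class = "pipeline_config")
}

#' Extract Lives_In events from a document
#'
#' Runs the multi-pass sieve pipeline: trigger detection, modality
#' filtering, intra-clause pattern extraction (or externally supplied
#' intra-sentence predictions), event-label propagation, cross-clause
#' trigger inference, and cross-sentence trigger inference inside
#' bacteria-anchored context windows. The output is deterministic: no step
#' involves randomness.
#'
#' @param doc an `annotated_doc`; analyzed in place when `$tokens` is
#'   `NULL` (gold parses attached by the fixture loaders count as
#'   analyzed).
#' @param config a [pipeline_config()].
#' @param conllu optional gold parse forwarded to [analyze()].
#' @return a `lives_in_result`: list with `events` (tibble `bacteria_id`,
#'   `location_id`, `provenance`, `sentence_span`), `doc_id`, `triggers`,
#'   `blocked_ids` and per-sieve counts (`sieve_counts`).
#' @export
extract_events <- function(doc, config = pipeline_config(), conllu = NULL) {
  stopifnot(inherits(doc, "annotated_doc"))
  if (is.null(doc$tokens) || !is.null(conllu)) {
    doc <- analyze(doc, backend = config$backend, conllu = conllu)
  }
  if (is.null(doc$alignment)) doc$alignment <- align_mentions(doc)
  lp <- config$loc_preps

  triggers <- if (is.null(config$lexicon)) {
    detect_triggers(doc, new_lexicon(character(), integer(), character()))
  } else {
    detect_triggers(doc, config$lexicon)
  }

  blocked_ids <- character(0)
  if (config$modality) {
    blk <- find_blocked_tokens(doc)
    flt <- apply_modality_filter(doc, triggers, blk)
    blocked_ids <- flt$blocked_ids
    triggers <- flt$triggers
  }

  if (!is.null(config$external_intra)) {
    intra <- config$external_intra
    if (is.character(intra)) {
      rel <- parse_a2(readLines(intra, warn = FALSE), doc$entities)
      intra <- rel$events
    }
    intra <- tibble::tibble(bacteria_id = intra$bacteria_id,
                            location_id = intra$location_id,
                            provenance = "external")
    after_intra <- dedupe_events(intra)
    after_cc <- after_intra
  } else {
    intra <- extract_intra_clause(doc, blocked_ids, lp)
    after_intra <- propagate(doc, intra, blocked_ids = blocked_ids)
    linked <- link_triggers(doc, triggers, scope = "intra",
                            bacteria_ids_use = setdiff(bacteria_ids(doc),
                                                       blocked_ids))
    after_cc <- infer_cross_clause(doc, linked, after_intra, blocked_ids, lp)
    after_cc <- propagate(doc, after_cc, blocked_ids = blocked_ids)
  }

  final <- infer_cross_sentence(doc, triggers, after_cc,
                                window_size = config$window_size,
                                blocked_ids = blocked_ids, loc_preps = lp)
  final <- stratify_events(doc, dedupe_events(final))
  structure(list(
    doc_id = doc$doc_id,
    events = final,
    triggers = triggers,
    blocked_ids = blocked_ids,
    sieve_counts = tibble::tibble(
      sieve = c("intra_clause", "propagation", "cross_clause",
                "cross_sentence"),
      events = c(nrow(intra), nrow(after_intra), nrow(after_cc), nrow(final))
    ),
    doc = doc
  ), class = "lives_in_result")
}

#' Preset extraction modes
#'
#' The five ablation configurations: `M1` intra-clause patterns only; `M2`
#' adds trigger inference with the training-data lexicon; `M3` uses the
#' unlabeled-data lexicon; `M4` replaces rule-based intra-sentence
#' extraction with externally supplied predictions and keeps trigger-based
#' cross-sentence inference; `M5` is `M4` without modality filtering.
#'
#' @param mode one of `"M1"`..`"M5"`.
#' @param external_intra external intra-sentence predictions (required for
#'   M4/M5).
#' @param ... further arguments to [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
mode_config <- function(mode = c("M3", "M1", "M2", "M4", "M5"),
                        external_intra = NULL, ...) {
  mode <- match.arg(mode)
  switch(mode,
    M1 = pipeline_config(lexicon = NULL, ...),
    M2 = pipeline_config(lexicon = "train", ...),
    M3 = pipeline_config(lexicon = "unlabeled", ...),
    M4 = pipeline_config(lexicon = "unlabeled",
                         external_intra = external_intra, ...),
    M5 = pipeline_config(lexicon = "unlabeled",
                         external_intra = external_intra, modality = FALSE,
                         ...)
  )
}

#' @export
print.lives_in_result <- function(x, ...) {
  cat(sprintf("<lives_in_result '%s': %d events (%d intra, %d cross), %d triggers>\n",
              x$doc_id, nrow(x$events),
              sum(x$events$sentence_span == "intra"),
              sum(x$events$sentence_span == "cross"),
              nrow(x$triggers)))
  invisible(x)
}

#' Tidy a pipeline result
#'
#' @param x a `lives_in_result`.
#' @param ... unused.
#' @return the events tibble, one row per extracted event.
#' @export
tidy.lives_in_result <- function(x, ...) x$events

#' One-row summary of a pipeline result
#'
#' @param x a `lives_in_result`.
#' @param ... unused.
#' @return tibble with event, trigger and blocked-mention counts.
#' @export
glance.lives_in_result <- function(x, ...) {
  tibble::tibble(
    doc_id = x$doc_id,
    n_events = nrow(x$events),
    n_intra = sum(x$events$sentence_span == "intra"),
    n_cross = sum(x$events$sentence_span == "cross"),
    n_triggers = nrow(x$triggers),
    n_blocked = length(x$blocked_ids)
  )
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' @export
tidy.eval_report <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.eval_report <- function(x, ...) {
  all_row <- x[x$stratum == "all", ]
  tibble::tibble(precision = all_row$precision, recall = all_row$recall,
                 f1 = all_row$f1)
}
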