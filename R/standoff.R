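#' Read a BioNLP-ST standoff document
#'
#' Loads a document from the standoff triple used by the Bacteria-Biotope
#' event task: a `.txt` file with the raw text, an `.a1` file with entity
#' mentions (`T` lines, possibly with discontinuous `;`-separated spans) and
#' an optional `.a2` file with `Lives_In` relations (`R` lines) and `Equiv`
#' declarations (`*` lines). Only the three event-relevant entity types
#' (`Bacteria`, `Habitat`, `Geographical`) are kept; other annotation types
#' such as `Title` or `Paragraph` are skipped silently.
#'
#' Character offsets are 0-based, half-open, counted on the raw text with
#' newlines intact. The surface text of a discontinuous mention is compared
#' against the fragments joined by one space; a mismatch raises a warning
#' (source files vary in this detail), while a mismatch on a contiguous span
#' is an integrity error.
#'
#' @param txt path to the `.txt` file, or a length-1 character string of raw
#'   text when `text_is_literal = TRUE`.
#' @param a1 path to the `.a1` file, or a character vector of `.a1` lines
#'   when `text_is_literal = TRUE`.
#' @param a2 optional path to (or literal lines of) the `.a2` file.
#' @param doc_id document identifier; defaults to the `.txt` file name.
#' @param text_is_literal interpret `txt`/`a1`/`a2` as content, not paths.
#' @return An object of class `annotated_doc`: a list with `doc_id`, `text`,
#'   `entities` (tibble: `id`, `type`, `start`, `end`, `surface`, `spans`
#'   list-column of per-fragment tibbles), `equiv` (list of character
#'   vectors of mutually equivalent entity ids), `gold_events` (tibble:
#'   `bacteria_id`, `location_id`) and `tokens` (`NULL` until [analyze()]).
#' @seealso [write_predictions()], [analyze()], [extract_events()]
#' @export
read_document <- function(txt, a1, a2 = NULL, doc_id = NULL,
                          text_is_literal = FALSE) {
  if (text_is_literal) {
    text <- paste(txt, collapse = "\n")
    a1_lines <- a1
    a2_lines <- a2
    if (is.null(doc_id)) doc_id <- "doc"
  } else {
    text <- read_text_file(txt)
    a1_lines <- readLines(a1, warn = FALSE, encoding = "UTF-8")
    a2_lines <- if (!is.null(a2)) readLines(a2, warn = FALSE, encoding = "UTF-8")
    if (is.null(doc_id)) doc_id <- sub("\\.txt$", "", basename(txt))
  }
  entities <- parse_a1(a1_lines, text)
  rel <- parse_a2(a2_lines, entities)
  doc <- structure(
    list(doc_id = doc_id, text = text, entities = entities,
         equiv = rel$equiv, gold_events = rel$events, tokens = NULL),
    class = "annotated_doc"
  )
  doc
}

read_text_file <- function(path) {
  raw <- readChar(path, file.size(path), useBytes = FALSE)
  Encoding(raw) <- "UTF-8"
  # keep interior newlines; strip a single trailing newline added by editors
  sub("\n$", "", raw)
}

entity_types <- c("Bacteria", "Habitat", "Geographical")
location_types <- c("Habitat", "Geographical")

parse_a1 <- function(lines, text) {
  lines <- lines[nzchar(trimws(lines))]
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (!grepl("^T", parts[[1]]) || length(parts) < 3) {
      stop(sprintf("a1 parse error at line %d: %s", i, ln), call. = FALSE)
    }
    header <- strsplit(parts[[2]], " ", fixed = TRUE)[[1]]
    type <- header[[1]]
    if (!type %in% entity_types) next
    offs <- paste(header[-1], collapse = " ")
    frags <- strsplit(offs, ";", fixed = TRUE)[[1]]
    spans <- purrr::map(frags, function(f) {
      se <- suppressWarnings(as.integer(strsplit(trimws(f), " ")[[1]]))
      if (length(se) != 2 || anyNA(se) || se[1] >= se[2]) {
        stop(sprintf("a1 parse error at line %d: bad span '%s'", i, f),
             call. = FALSE)
      }
      tibble::tibble(start = se[1], end = se[2])
    })
    spans <- dplyr::bind_rows(spans)
    if (is.unsorted(spans$start, strictly = TRUE)) {
      stop(sprintf("a1 parse error at line %d: spans not strictly increasing", i),
           call. = FALSE)
    }
    if (any(spans$end[-nrow(spans)] > spans$start[-1])) {
      stop(sprintf("a1 parse error at line %d: overlapping spans", i),
           call. = FALSE)
    }
    if (max(spans$end) > nchar(text) || min(spans$start) < 0) {
      stop(sprintf("a1 integrity error at line %d: span outside text", i),
           call. = FALSE)
    }
    covered <- paste(
      purrr::map_chr(seq_len(nrow(spans)),
                     ~ substr(text, spans$start[.x] + 1L, spans$end[.x])),
      collapse = " "
    )
    surface <- parts[[3]]
    if (!identical(covered, surface)) {
      if (nrow(spans) > 1) {
        warning(sprintf("a1 line %d: discontinuous surface mismatch ('%s' vs '%s')",
                        i, covered, surface), call. = FALSE)
      } else {
        stop(sprintf("a1 integrity error at line %d: text '%s' does not match span text '%s'",
                     i, surface, covered), call. = FALSE)
      }
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id = parts[[1]], type = type,
      start = min(spans$start), end = max(spans$end),
      surface = covered, spans = list(spans)
    )
  }
  if (length(rows) == 0) {
    return(tibble::tibble(id = character(), type = character(),
                          start = integer(), end = integer(),
                          surface = character(), spans = list()))
  }
  dplyr::bind_rows(rows)
}

parse_a2 <- function(lines, entities) {
  events <- tibble::tibble(bacteria_id = character(), location_id = character())
  equiv <- list()
  if (is.null(lines)) return(list(events = events, equiv = equiv))
  lines <- lines[nzchar(trimws(lines))]
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2) {
      stop(sprintf("a2 parse error at line %d: %s", i, ln), call. = FALSE)
    }
    fields <- strsplit(parts[[2]], " ", fixed = TRUE)[[1]]
    if (identical(substr(parts[[1]], 1, 1), "*")) {
      if (!identical(fields[[1]], "Equiv") || length(fields) < 3) {
        stop(sprintf("a2 parse error at line %d: bad Equiv", i), call. = FALSE)
      }
      members <- fields[-1]
      if (any(unlist(equiv) %in% members)) {
        stop(sprintf("a2 integrity error at line %d: Equiv sets not disjoint", i),
             call. = FALSE)
      }
      equiv[[length(equiv) + 1L]] <- members
    } else if (grepl("^R", parts[[1]])) {
      if (!identical(fields[[1]], "Lives_In") || length(fields) != 3) {
        stop(sprintf("a2 parse error at line %d: %s", i, ln), call. = FALSE)
      }
      args <- stats::setNames(
        sub("^[^:]+:", "", fields[-1]),
        sub(":.*$", "", fields[-1])
      )
      if (!all(c("Bacteria", "Location") %in% names(args))) {
        stop(sprintf("a2 parse error at line %d: missing role", i), call. = FALSE)
      }
      check_event_roles(args[["Bacteria"]], args[["Location"]], entities, i)
      events <- dplyr::bind_rows(events, tibble::tibble(
        bacteria_id = unname(args[["Bacteria"]]),
        location_id = unname(args[["Location"]])
      ))
    } else {
      stop(sprintf("a2 parse error at line %d: unknown annotation '%s'",
                   i, parts[[1]]), call. = FALSE)
    }
  }
  list(events = events, equiv = equiv)
}

check_event_roles <- function(bid, lid, entities, line_no) {
  tb <- entities$type[match(bid, entities$id)]
  tl <- entities$type[match(lid, entities$id)]
  if (is.na(tb) || is.na(tl)) {
    stop(sprintf("a2 integrity error at line %d: dangling entity id", line_no),
         call. = FALSE)
  }
  if (!identical(tb, "Bacteria") || !tl %in% location_types) {
    stop(sprintf("a2 integrity error at line %d: role/type mismatch (%s, %s)",
                 line_no, tb, tl), call. = FALSE)
  }
  invisible(NULL)
}

#' Write predicted events in a2 format
#'
#' Serialises a set of Lives_In events as BioNLP-ST `.a2` relation lines,
#' `R1..Rk` numbered in input order. Reading the output back with
#' [read_document()] reproduces the event set exactly.
#'
#' @param doc an `annotated_doc` whose entities the events reference.
#' @param events tibble with columns `bacteria_id`, `location_id`.
#' @param path optional file path; when `NULL` the lines are returned.
#' @return (invisibly, when writing) the character vector of a2 lines.
#' @export
write_predictions <- function(doc, events, path = NULL) {
  stopifnot(inherits(doc, "annotated_doc"))
  if (nrow(events) > 0) {
    missing <- setdiff(c(events$bacteria_id, events$location_id), doc$entities$id)
    if (length(missing) > 0) {
      stop("dangling entity id(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  lines <- character(0)
  if (nrow(events) > 0) {
    lines <- sprintf("R%d\tLives_In Bacteria:%s Location:%s",
                     seq_len(nrow(events)), events$bacteria_id,
                     events$location_id)
  }
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(lines))
  }
  lines
}

#' @export
print.annotated_doc <- function(x, ...) {
  cat(sprintf("<annotated_doc '%s': %d chars, %d entities, %d gold events%s>\n",
              x$doc_id, nchar(x$text), nrow(x$entities), nrow(x$gold_events),
              if (is.null(x$tokens)) "" else sprintf(", %d tokens (parsed)",
                                                    nrow(x$tokens))))
  invisible(x)
}

# entity ids of a given role
bacteria_ids <- function(doc) doc$entities$id[doc$entities$type == "Bacteria"]
location_ids <- function(doc) doc$entities$id[doc$entities$type %in% location_types]
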