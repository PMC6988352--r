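# Porter (1980) stemming, used for trigger detection so that verb and
# adjective tokens match noun lemmas in the lexicon (persist ~ persistence).

porter_cons <- function(w, i) {
  ch <- substr(w, i, i)
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1) return(TRUE)
    return(!porter_cons(w, i - 1L))
  }
  TRUE
}

# measure m of the stem: number of VC sequences
porter_m <- function(w) {
  n <- nchar(w)
  if (n == 0) return(0L)
  shapes <- vapply(seq_len(n), function(i) porter_cons(w, i), logical(1))
  rle_s <- rle(shapes)$values
  # count TRUE (consonant) runs that follow a vowel run
  m <- 0L
  seen_vowel <- FALSE
  for (v in rle_s) {
    if (!v) seen_vowel <- TRUE
    else if (seen_vowel) { m <- m + 1L; seen_vowel <- FALSE }
  }
  m
}

porter_has_vowel <- function(w) {
  n <- nchar(w)
  n > 0 && any(!vapply(seq_len(n), function(i) porter_cons(w, i), logical(1)))
}

porter_double_cons <- function(w) {
  n <- nchar(w)
  n >= 2 && substr(w, n, n) == substr(w, n - 1, n - 1) && porter_cons(w, n)
}

# *o: stem ends cvc where the final c is not w, x or y
porter_cvc <- function(w) {
  n <- nchar(w)
  if (n < 3) return(FALSE)
  if (!porter_cons(w, n) || porter_cons(w, n - 1L) || !porter_cons(w, n - 2L)) {
    return(FALSE)
  }
  !substr(w, n, n) %in% c("w", "x", "y")
}

ends_with <- function(w, s) {
  nchar(w) >= nchar(s) && substr(w, nchar(w) - nchar(s) + 1L, nchar(w)) == s
}
chop <- function(w, k) substr(w, 1L, nchar(w) - k)

# replace suffix when the remaining stem satisfies a measure condition
porter_rule <- function(w, suf, rep, cond) {
  stem <- chop(w, nchar(suf))
  if (cond(stem)) paste0(stem, rep) else w
}

#' Porter stem of a word
#'
#' Classic Porter (1980) suffix-stripping, as used when comparing document
#' tokens against trigger-lexicon lemmas.
#'
#' @param word character vector of words (lower-cased internally).
#' @return character vector of stems.
#' @export
porter_stem <- function(word) {
  vapply(tolower(word), porter_stem1, character(1), USE.NAMES = FALSE)
}

porter_stem1 <- function(w) {
  if (nchar(w) <= 2) return(w)

  # step 1a
  if (ends_with(w, "sses")) w <- chop(w, 2)
  else if (ends_with(w, "ies")) w <- chop(w, 2)
  else if (!ends_with(w, "ss") && ends_with(w, "s")) w <- chop(w, 1)

  # step 1b
  if (ends_with(w, "eed")) {
    if (porter_m(chop(w, 3)) > 0) w <- chop(w, 1)
  } else {
    hit <- FALSE
    if (ends_with(w, "ed") && porter_has_vowel(chop(w, 2))) {
      w <- chop(w, 2); hit <- TRUE
    } else if (ends_with(w, "ing") && porter_has_vowel(chop(w, 3))) {
      w <- chop(w, 3); hit <- TRUE
    }
    if (hit) {
      if (ends_with(w, "at") || ends_with(w, "bl") || ends_with(w, "iz")) {
        w <- paste0(w, "e")
      } else if (porter_double_cons(w) &&
                 !substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z")) {
        w <- chop(w, 1)
      } else if (porter_m(w) == 1 && porter_cvc(w)) {
        w <- paste0(w, "e")
      }
    }
  }

  # step 1c
  if (ends_with(w, "y") && porter_has_vowel(chop(w, 1))) {
    w <- paste0(chop(w, 1), "i")
  }

  # step 2
  s2 <- c(ational = "ate", tional = "tion", enci = "ence", anci = "ance",
          izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
          ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
          alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
          aliti = "al", iviti = "ive", biliti = "ble")
  for (suf in names(s2)) {
    if (ends_with(w, suf)) {
      w <- porter_rule(w, suf, s2[[suf]], function(s) porter_m(s) > 0)
      break
    }
  }

  # step 3
  s3 <- c(icate = "ic", ative = "", alize = "al", iciti = "ic", ical = "ic",
          ful = "", ness = "")
  for (suf in names(s3)) {
    if (ends_with(w, suf)) {
      w <- porter_rule(w, suf, s3[[suf]], function(s) porter_m(s) > 0)
      break
    }
  }

  # step 4
  s4 <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant", "ement",
          "ment", "ent", "ou", "ism", "ate", "iti", "ous", "ive", "ize")
  for (suf in s4) {
    if (ends_with(w, suf)) {
      stem <- chop(w, nchar(suf))
      if (suf == "ion") next
      if (porter_m(stem) > 1) w <- stem
      break
    }
  }
  if (ends_with(w, "ion")) {
    stem <- chop(w, 3)
    if (porter_m(stem) > 1 && nchar(stem) > 0 &&
        substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t")) {
      w <- stem
    }
  }

  # step 5a
  if (ends_with(w, "e")) {
    stem <- chop(w, 1)
    m <- porter_m(stem)
    if (m > 1 || (m == 1 && !porter_cvc(stem))) w <- stem
  }
  # step 5b
  if (porter_m(w) > 1 && porter_double_cons(w) && ends_with(w, "l")) {
    w <- chop(w, 1)
  }
  w
}

# ---------------------------------------------------------------------------
# Lemmatization + nominalization of candidate triggers.

# derivational verb/adjective -> noun table covering the domain vocabulary;
# keys are verb lemmas or adjectives, values the related noun
derivational_nouns <- c(
  colonize = "colonization", eliminate = "elimination", infect = "infection",
  attach = "attachment", adhere = "adhesion", grow = "growth",
  resist = "resistance", detect = "detection", transmit = "transmission",
  expose = "exposure", survive = "survival", respond = "response",
  contaminate = "contamination", persist = "persistence",
  isolate = "isolation", enrich = "enrichment", carry = "carriage",
  prevail = "prevalence", abound = "abundance", determine = "determination",
  analyze = "analysis", examine = "examination", evaluate = "evaluation",
  assess = "assessment", investigate = "investigation",
  inspect = "inspection", emerge = "emergence", occur = "occurrence",
  infest = "infestation", culture = "culture", harbor = "harbor",
  recover = "recovery", purify = "purification",
  susceptible = "susceptibility", resistant = "resistance",
  prevalent = "prevalence", abundant = "abundance", adherent = "adhesion",
  infected = "infection", contaminated = "contamination",
  colonized = "colonization", infectious = "infection",
  pathogenic = "pathogen"
)

irregular_singulars <- c(
  analyses = "analysis", hypotheses = "hypothesis", diagnoses = "diagnosis",
  feces = "feces", species = "species", bacteria = "bacteria",
  salmonellae = "salmonellae", abscesses = "abscess", viruses = "virus"
)

singularize <- function(w) {
  if (w %in% names(irregular_singulars)) return(unname(irregular_singulars[w]))
  if (grepl("ies$", w) && nchar(w) > 4) return(sub("ies$", "y", w))
  if (grepl("(ss|us|is)$", w)) return(w)
  if (grepl("(ch|sh|x|z|s)es$", w)) return(sub("es$", "", w))
  if (grepl("s$", w)) return(sub("s$", "", w))
  w
}

# strip inflection down to a dictionary-ish verb lemma
verb_lemma <- function(w) {
  if (grepl("ies$", w)) return(sub("ies$", "y", w))
  if (grepl("ied$", w)) return(sub("ied$", "y", w))
  for (suf in c("ing", "ed", "es", "s")) {
    if (grepl(paste0(suf, "$"), w) && nchar(w) - nchar(suf) >= 3) {
      stem <- sub(paste0(suf, "$"), "", w)
      # undouble final consonant (occurring -> occur)
      if (grepl("([b-df-hj-np-tv-z])\\1$", stem)) {
        und <- substr(stem, 1, nchar(stem) - 1)
        if (paste0(und, "e") %in% names(derivational_nouns)) return(paste0(und, "e"))
        if (und %in% names(derivational_nouns)) return(und)
      }
      if (stem %in% names(derivational_nouns)) return(stem)
      if (paste0(stem, "e") %in% names(derivational_nouns)) return(paste0(stem, "e"))
      return(stem)
    }
  }
  w
}

#' Normalize a candidate trigger token to its lexicon lemma
#'
#' Lower-cases, lemmatizes, and nominalizes: plural nouns are singularized;
#' verbs and adjectives are mapped to a derivationally related noun when one
#' is known (e.g. "colonized" to "colonization"), otherwise the bare lemma is
#' kept.
#'
#' @param surface token surface form(s).
#' @param upos coarse part of speech (`NOUN`, `VERB`, `ADJ`), recycled.
#' @return character vector of normalized lemmas.
#' @export
normalize_trigger <- function(surface, upos = "NOUN") {
  n <- max(length(surface), length(upos))
  surface <- rep_len(tolower(surface), n)
  upos <- rep_len(upos, n)
  vapply(seq_len(n), function(i) {
    w <- surface[[i]]
    if (w %in% names(derivational_nouns)) return(unname(derivational_nouns[w]))
    if (upos[[i]] == "NOUN") return(singularize(w))
    lem <- verb_lemma(w)
    if (lem %in% names(derivational_nouns)) return(unname(derivational_nouns[lem]))
    lem
  }, character(1))
}

# words the trigger collector discards, from the two keyword classes:
# research purpose/method terms and amount/class-of-bacteria terms
stop_class_research <- c(
  "analysis", "study", "examination", "evaluation", "inspection",
  "assessment", "investigation", "determination"
)
stop_class_amount <- c(
  "any", "some", "part", "number", "amount", "frequency", "type", "pattern",
  "class", "group", "range", "change", "increase", "decrease"
)

#' Remove non-trigger lemmas
#'
#' Drops lemmas belonging to the two curated non-trigger classes: research
#' purpose/method words (analysis, study, evaluation, ...) and amount/class
#' words (any, range, increase, ...). Extra user-supplied stop lemmas may be
#' appended.
#'
#' @param lemmas character vector of candidate lemmas.
#' @param extra_stop optional additional lemmas to drop.
#' @return the retained lemmas.
#' @export
filter_non_triggers <- function(lemmas, extra_stop = character(0)) {
  setdiff(lemmas, c(stop_class_research, stop_class_amount, extra_stop))
}
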