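---
title: "Extracting Lives_In events with context triggers: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting Lives_In events with context triggers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triggersieve)
library(dplyr)
```

## The problem

Bacteria-biotope extraction asks, for a biomedical abstract in which human
annotators have already marked every *Bacteria*, *Habitat* and
*Geographical* mention, which (bacteria, location) pairs stand in a
`Lives_In` relation. Roughly a quarter of the true relations cross a
sentence boundary, where no syntactic path connects the two mentions, and
the available labeled corpora (tens of documents) are far too small to
train a reliable supervised model of that reasoning. `triggersieve`
implements an unsupervised, linguistically motivated alternative: a
multi-pass sieve of rule stages ordered by decreasing precision.

The central device is the **context trigger** — a noun such as *carriage*,
*infection* or *colonization* whose very occurrence implies the presence of
a nearby-mentioned bacterium, much like an indirect anaphor. In

> *None of the colonized children experienced an invasive* **K. kingae**
> *infection. The prevalence of* **pharyngeal** *carriage among surgical
> patients was 8.0%.*

the word *carriage* in the second sentence points back to *K. kingae* and
forward (syntactically) to *pharyngeal*, so the cross-sentence relation is
recovered by transitivity: bacteria → trigger → location.

## The sieves

1. **Trigger detection.** Every noun, verb or adjective token outside an
   annotated mention whose Porter stem equals the stem of a lexicon lemma
   is a trigger occurrence (so the verb *persist* matches the lemma
   *persistence*).
2. **Modality filtering.** Mentions and triggers that are dependency
   descendants of a hypothesis/research-goal keyword (*evaluate*, *study*,
   *determine*, ...), sit inside an *if*/*whether* clause, or are directly
   negated (*no*, *not*, *none of*, or a *not*-negated governing
   predicate) are removed before any inference step sees them. Filtering
   is purely subtractive and per-mention.
3. **Intra-clause patterns.** Six dependency configurations extract
   high-precision same-clause events: the three trigger patterns
   P1 "{noun} *of* [B] *loc_prep* [L]", P2 "[B] {n/v/p} *loc_prep* [L]",
   P3 "[L] {n/v/p} *prep* [B]" (with the location slot now required to be
   an annotated mention), plus N1 (both mentions inside one noun phrase),
   N2 (one mention's character span nested in the other's) and N3 (a
   direct prepositional edge between the mention heads).
4. **Propagation.** A confirmed event extends along five same-type mention
   relations — nesting, coordination, apposition (including parenthesized
   abbreviations), comma-joined geographical hierarchy (smaller region to
   larger), and participle-preposition linking — applied on both the
   bacteria and location side, iterated to a fixpoint. The closure is
   idempotent and independent of rule application order; both properties
   are asserted by tests over randomized fixtures.
5. **Cross-clause inference.** Each trigger is linked to the bacteria
   mention nearest by word count in its sentence (ties to the preceding
   mention); every location the trigger reaches through an intra-clause
   pattern becomes an event of the linked bacteria.
6. **Cross-sentence inference.** Candidate bacteria are those whose
   sentence holds no location at all or that already have an
   intra-sentence event; candidate locations are those without any
   intra-sentence event. Each candidate bacteria anchors a context window
   of up to three sentences either side, truncated before any sentence
   containing another bacteria mention (no window at all if a second
   bacteria shares the anchor's sentence). Triggers inside the window
   whose nearest bacteria (sentence distance first, then word distance,
   ties to the preceding mention) is the anchor mediate events to
   candidate locations exactly as in step 5, followed by a final
   propagation pass.

With externally produced intra-sentence predictions (an `.a2` file from
any supervised extractor), steps 3–5 are replaced by those predictions and
only cross-sentence inference runs on top — the `M4`/`M5` modes of
`mode_config()`. Supplied events are never discarded by the
candidate-location constraint.

## Trigger lexicons

A lexicon is mined from plain text by `compile_lexicon()`: candidate
sentences must contain a gazetteer bacteria name (case-insensitive longest
match, so *campylobacter jejuni* beats *campylobacter*) and at least one
preposition; the P1–P3 patterns are then matched with the location slot
unconstrained — the locational preposition alone (*in, on, to, from, at*)
restricts its semantics, so unlabeled text needs no location annotations.
Matched slot fillers are lower-cased, lemmatized and nominalized
(*colonized* → *colonization*) via an internal derivational table, the two
curated non-trigger classes are removed (research-method words such as
*analysis*, *evaluation*; amount/class words such as *range*, *increase*),
and a frequency threshold is applied — 1 for training-data-sized corpora,
300 for large unlabeled harvests, both as published.

The packaged lexicons transcribe the published table:
`load_packaged_lexicon("train")` has all 15 training-data lemmas;
`"unlabeled"` has the 20 printed most-frequent lemmas with their corpus
frequencies plus the 7 training lemmas known to belong to the full 47-lemma
list but whose frequencies were never printed — these carry the threshold
value 300 and `placeholder = TRUE`. The remaining 20 of the 47 are not
recoverable from the publication; any analysis using the packaged lexicon
inherits that gap.

## Parsing backends

Every sieve consumes one tokens tibble per document (sentence index, token
index, surface, lemma, universal POS, head, dependency relation, character
offsets). Two backends produce it behind the single `analyze()` interface:

* **`"conllu"`** reads a gold parse. All packaged worked examples ship
  with hand-written Universal Dependencies parses, and the synthetic
  generator emits its own gold parses, so the entire test surface is
  parser-independent — deliberately so, since pattern semantics rather
  than any specific parser's label choices are what the rules encode. The
  original system used a Stanford-dependencies parser; the patterns here
  are stated in UD terms, and borderline clause-boundary decisions can
  differ between the two schemes.
* **`"heuristic"`** is a small deterministic tokenizer, closed-class/suffix
  POS tagger and right-branching NP/PP attacher. It parses the simple
  declarative shapes the trigger patterns target ("*Elimination of
  Helicobacter pylori in the antrum was reported.*") and backs plain-text
  trigger mining; it is not adequate for complex clausal syntax, which is
  why extraction quality on arbitrary raw text depends on supplying real
  parses in CoNLL-U form.

Clause boundaries are operationalized as the relation set {`ccomp`,
`xcomp`, `advcl`, `acl`, `acl:relcl`, `csubj`, `parataxis`, `conj` between
verbs}; a mention's head token is the covered token governed from outside
the mention (falling back to the last token). A mention crossing a
predicted sentence boundary forces the two sentences to merge, so
alignment is always total.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_frequency` | 1 (train) / 300 (unlabeled) | lexicon inclusion threshold, in corpus occurrences |
| `window_size` | 3 sentences | context-window half-width around a candidate bacteria |
| locational prepositions | in, on, to, from, at | constrain the location slot of P1/P2 (`extended_preps` adds within/into/onto) |
| `modality` | on | hypothesis/negation/goal filtering |
| tie-break | preceding mention | trigger-to-bacteria links at equal distance |

The threshold and window size are the published operating point; they are
inputs to the method, not tuned here. The preposition list is open-ended
in the source ("such as ..."); the default keeps exactly the five listed
forms.

## Design choices made where the source was open

* **Trigger-link direction.** The source states both "each bacteria is
  mapped to its closest trigger" and "each trigger is linked to its
  closest bacteria", which conflict when several of each co-occur. The
  package links each *trigger* to its nearest bacteria at both scopes —
  the direction its cross-sentence procedure spells out — and computes
  nearest over all document bacteria, keeping a trigger for a window only
  when its nearest is the anchor.
* **Modality keywords match exact surface forms.** The keyword list
  enumerates nominal and verbal forms explicitly; stem matching would let
  incidental inflections (e.g. a passive "*were studied*" as the root of a
  sentence) suppress every mention in it, destroying correct
  cross-sentence extractions. Consequently inflected keyword variants do
  not block — a documented limitation.
* **Propagation at event level.** Table-level propagation is described
  over bacteria-location *and* trigger-location pairs; here trigger links
  are converted to events first and the closure runs once over events.
  The resulting fixpoint is the same, and provenance stays attached to
  pairs.
* **Known over-generation accepted.** Nesting and participle-preposition
  propagation ignore the annotation guidelines' transitivity constraints
  (living organism vs. environment), and the negation rule mishandles the
  "None of the colonized children ..." construction exactly as the
  original system does. Both error modes are reproduced deliberately, not
  patched, and surface in the packaged examples.
* **Equal-extent nesting.** Discontinuous mentions are compared by overall
  character extent, so a discontinuous mention and the phrase covering it
  count as nested — required for coordinated-ellipsis families like
  *apple (surfaces) and lettuce surfaces*.

## The synthetic generator

`generate_corpus()` instantiates thirteen sentence templates — one per
extraction pattern (P1–P3, N1–N3), one per propagation rule (R1–R5), a
two-sentence cross-trigger document, and a modality-negative document whose
pattern sits under "*To evaluate ...*" and therefore entails no gold
events. Vocabulary pools hold only names that appear in the task's
literature (*Helicobacter pylori*, *Kingella kingae*, ..., *antrum*,
*sediments*, *tryptic soy broth*, *Georgia, USA*). Each document carries
its own gold parse and exactly the gold events its template entails, and
generation is byte-identical under a fixed seed without disturbing the
caller's RNG stream.

The templates are rule-coverage instruments. They emulate the syntactic
configurations the sieves target with clean parses and unambiguous gold
labels; they do not emulate discourse structure, parser noise, coreference,
generic-vs-specific mention distinctions, or the class imbalance of real
abstracts. Perfect precision/recall on template corpora therefore shows
that each rule is individually reachable and correct — not that real-corpus
scores would be reproduced, which additionally require the official hidden
test labels, the full unlabeled trigger harvest, and a retrained supervised
intra-sentence system, all outside this package's scope.

## Numerical conventions and degenerate inputs

Precision, recall and F1 are percentages; each is 0 when its denominator
is 0, F1 is computed from unrounded precision and recall, and all three
are reported rounded half-up at one decimal (reproducing e.g. 58.15 →
58.2). Event matching deduplicates pairs and treats Equiv-declared mention
ids as interchangeable. Empty documents, empty lexicons, empty candidate
sets and empty corpora all yield empty results (with a warning for an
empty mining corpus). Character offsets are 0-based and half-open
throughout; a surface-text mismatch on a contiguous span is a fatal
integrity error, on a discontinuous span a warning.

## Problem sizes used in the checks

The shipped test suite and acceptance script run on the transcribed worked
examples (documents of 1–3 sentences), template corpora of a few dozen
documents, randomized trees of about a dozen tokens for the predicate
oracles, and twenty randomized window layouts — sizes chosen so every
property can be verified against brute-force oracles exactly.

## A worked run

```{r example}
ex <- load_paper_examples("ex01")[[1]]
res <- extract_events(ex, pipeline_config(lexicon = "unlabeled"))
tidy(res)
glance(res)
evaluate_events(ex, res$events) |> tidy()
```
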