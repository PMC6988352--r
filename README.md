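# triggersieve

Unsupervised extraction of **Lives_In** events between bacteria and their
physical locations (habitats and geographical places) in biomedical text,
in the BioNLP-ST Bacteria-Biotope standoff setting: entity mentions are
given (`.a1` files over raw `.txt`), the system predicts binary relations
(`.a2`). The package is aimed at biomedical text-mining researchers who
need a reproducible rule-based baseline that — unlike most supervised
systems for this task — also recovers relations that **cross sentence
boundaries**.

## The method

The extractor is a multi-pass sieve ordered by decreasing precision. Its
core device is the *context trigger*: a lemma t (e.g. *carriage*,
*infection*) whose occurrence implies the presence of a nearby bacteria
mention. For a bacteria mention B, a trigger occurrence t, and a location
mention L,

    B — t    (t linked to its nearest bacteria; sentence distance, then
              word distance, ties to the preceding mention)
    t — L    (an intra-clause dependency pattern connects t and L)
    ⇒ Lives_In(B, L)

so cross-sentence relations reduce to intra-sentence ones. Around this
sit: six intra-clause dependency patterns (the trigger patterns
"{noun} of [B] loc_prep [L]", "[B] {n/v/p} loc_prep [L]",
"[L] {n/v/p} prep [B]" plus noun-phrase nesting, span nesting, and direct
prepositional attachment); a propagation closure that extends confirmed
events over nesting, coordination, apposition, geographical
comma-hierarchies and participle-preposition links until a fixpoint; a
modality filter that removes mentions dominated by hypothesis keywords,
inside *if*/*whether* clauses, or under negation; and bacteria-anchored
context windows of ±3 sentences, truncated at foreign bacteria mentions.
Trigger lexicons are mined from plain text with the same patterns
(location slot left unconstrained), normalized, stop-filtered and
frequency-thresholded; the published training-data (15 lemmas) and
unlabeled-corpus (20 printed of 47) lexicons ship with the package.
Scoring follows the shared task: a predicted pair is correct if it equals
(or is Equiv-equivalent to) a reference pair, with P/R/F1 reported overall
and split intra- vs cross-sentence.

## Worked example

The packaged two-sentence document `ex01` ("None of the colonized children
experienced an invasive K. kingae infection. The prevalence of pharyngeal
carriage among surgical patients was 8.0%.") has one Bacteria mention
(`T1`, *K. kingae*, sentence 1) and one Habitat mention (`T2`,
*pharyngeal*, sentence 2):

```r
library(triggersieve)
ex  <- load_paper_examples("ex01")[[1]]
res <- extract_events(ex, pipeline_config(lexicon = "unlabeled"))
tidy(res)
#> # A tibble: 1 × 4
#>   bacteria_id location_id provenance        sentence_span
#>   <chr>       <chr>       <chr>             <chr>
#> 1 T1          T2          cross_sentence:N1 cross
res$triggers
#> # A tibble: 4 × 5
#>   lemma        frequency sentence   tid surface
#>   <chr>            <int>    <int> <int> <chr>
#> 1 colonization      1015        1     4 colonized
#> 2 infection        12856        1    11 infection
#> 3 prevalence        3300        2     2 prevalence
#> 4 carriage           300        2     5 carriage
evaluate_events(ex, res$events) |> tidy()
#> # A tibble: 3 × 7
#>   stratum  gold predicted correct precision recall    f1
#> 1 intra       0         0       0         0      0     0
#> 2 cross       1         1       1       100    100   100
#> 3 all         1         1       1       100    100   100
```

The single extracted event is the cross-sentence pair (`T1`,`T2`): the
trigger *carriage* (detected by Porter-stem match against the lexicon)
links back to *K. kingae* — the only bacteria in its ±3-sentence window —
and forward to *pharyngeal*, which modifies it inside one noun phrase
(pattern N1). The evaluation row shows the prediction matches the
document's reference event exactly.

Other entry points: `compile_lexicon()` mines triggers from plain text
with a bacteria gazetteer; `generate_corpus(fixture_config(seed = 1))`
builds seeded synthetic standoff corpora with known gold events;
`mode_config("M1")`…`"M5"` reproduces the ablation ladder (patterns only →
+train triggers → +unlabeled triggers → external intra-sentence
predictions ± modality filtering); `autoplot()` charts results.

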