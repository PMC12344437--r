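---
title: "Mining organismal traits from taxonomic treatments: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining organismal traits from taxonomic treatments: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitmine)
```

## The task

Taxonomic treatments describe species in dense, semi-structured prose:
a taxon is named, its morphology, habitat and ecology are described, and
measurements are attached to body parts. `traitmine` decomposes the
extraction of this information into the standard text-mining stages —
named entity recognition (NER), entity normalisation (NEN) and
relationship extraction (RE) — over a four-type entity schema
(*arthropod*, *trait*, *value*, *qualifier*) and a typed relation schema
in which the relation label is fully determined by the entity types of the
ordered pair: arthropod→trait is `hasTrait`, trait→value is `hasValue`,
arthropod→qualifier is `hasQualifier`. Character offsets are 0-based and
half-open throughout, counted in Unicode code points, so an annotation's
surface is always `substr(text, start + 1, end)`.

The package deliberately implements every stage as a deterministic
baseline: a gazetteer tagger plus pattern grammar for NER, tiered string
matching for NEN, and a proximity rule for RE. Trained sequence or
relation models are treated as plugins that communicate through the same
formats the baselines use (BioC JSON for annotated documents, CoNLL/IOB2
for token sequences, JSON lines of context windows with head/tail offsets
for relation candidates), so a transformer-based tagger can replace any
baseline without touching the rest of the pipeline.

## Corpus representation and conversion

**BioC.** Documents arrive as BioC JSON collections. All passages of a
document are concatenated with a single `"\n"` separator — preserving the
sentence-boundary cue between passages — and all annotation offsets are
rebased into the concatenated coordinate system. On write, each document
is a single passage at offset zero, which makes the round trip exact; this
losslessness (text, spans, types, concept ids, scores, relations, split
tags) is property-tested.

**Tokens and sentences.** The tokenizer splits on whitespace and then
peels leading/trailing punctuation into one-character tokens, keeping
decimal numbers (`56.6`) and hyphenated compounds (`brownish-yellow`)
whole, because these are single value tokens in treatments. The sentence
splitter is rule-based — a boundary requires `.`, `!` or `?` followed by
whitespace and a capital or digit — with a guard list for the
abbreviations that pervade taxonomic prose: any single capital plus period
(genus abbreviations such as "T."), and "sp.", "spp.", "nov.", "cf.",
"e.g.", "i.e.", "Fig.", "al.", "ca.". No published splitter specification
exists for this corpus type, so a transparent rule with a documented guard
list was preferred over a statistical model.

**IOB2.** Converting the annotation layer to token labels assigns `B-`/`I-`
tags of an entity's type to every token whose span intersects the entity.
When an entity boundary falls inside a token the label expands to the whole
token — CoNLL is token-granular — while the character-accurate span stays
in the annotation layer. Converting back, ill-formed sequences are repaired
with the lenient semantics of the classic chunk evaluator: an orphan `I-X`
opens a chunk, and a type switch inside a run starts a new chunk. With
non-overlapping, token-aligned entities the round trip recovers the entity
multiset exactly (property-tested on generated corpora).

**Context windows.** Relation candidates are all typed pairs whose members
co-occur within `max_sentences` consecutive sentences (default 6). Whether
the original windows were strided or overlapping is not specified anywhere;
here each candidate pair gets the minimal window spanning both entities,
which yields exactly one window per in-range pair and, importantly,
produces the `none`-labelled pairs the RE stage needs as its negative
class. The long-range alternative extracts each entity with a `flank` of
surrounding characters and joins the two slices with a separator
(`" [SEP] "`), merging them without duplication when they overlap. The
flank default is 500 characters; 250 is an equally defensible choice and
both are plain parameters — the two figures circulate in descriptions of
this set-up, so neither is hard-coded.

## Dictionaries

The taxon dictionary is built from a Darwin-Core-style checklist by
extracting every row with `taxonomicStatus == "accepted"` that is
reachable downward from a configured root id. Reachability is computed
over accepted rows only, so a taxon whose parent chain passes through a
non-accepted name is excluded rather than silently re-parented. Each
concept stores its ascending lineage as names (nearest ancestor first, the
root's name included), matching how lineages are displayed and searched in
practice. Parent cycles are reported with the ids involved. The builder is
independent of input row order.

The trait dictionary is one concept per row: term, category (one of
*feeding ecology*, *habitat*, *morphology*), trait type (yes/no,
association, measurement, length/width, count), semicolon-separated
synonyms (trimmed, de-duplicated case-insensitively) and a source URI that
doubles as the concept id. Two curation helpers mirror how such
dictionaries are refined in practice: `filter_synonyms_by_frequency()`
drops synonyms attested fewer than `min_count` times (default 10) in a
reference corpus — counting whole-token, case-insensitive phrase
occurrences, never substrings, since the aim is to keep words actually
used in treatments — and `expand_plural_variants()` adds regular
plural/singular counterparts (`-s`, `-es` after sibilants, `-y`→`-ies`).
Words ending in *-s*/-*is* are left alone: Latin irregulars such as
*proboscis*/*proboscides* must come through the synonyms column, because a
naive rule would generate junk forms. The expansion is idempotent and
never touches taxon concepts.

## Tagging

The gazetteer tagger runs greedy longest match over the token sequence:
at each position the longest dictionary phrase wins and scanning resumes
after it. Each candidate phrase is matched in three tiers — exact surface,
case-folded, case-folded with the final token plural-stripped — except
that single-token taxon names match case-sensitively only: capitalisation
is informative for genus and higher-rank names, and folding them would
fire on common words (and lower-case text would fire on genera). Matches
carry the concept id and score 1.0; ambiguous surfaces resolve to the
lexicographically smallest concept id, deterministically.

Value mentions are recognised by a closed pattern grammar rather than a
trained model: number + unit measurements (units mm, cm, µm, m, km, g, mg,
kg, %), numeric ranges, runs of two or more comma-separated numbers
(treatments print measurement series such as "length 38, 47, 43, 41, 33,
21"; one run is one value span), bare numbers directly following a
measurement keyword (length, width, height, size, diameter), and colour
terms from a lexicon including `-ish` derivatives and hyphenated compounds.
Bare place-name values ("China") are a documented gap: the baseline ships
no location gazetteer. Qualifiers come from a closed lexicon (female,
male, juvenile, larva, adult, nymph, pupa).

Because the layers can overlap, `merge_annotations()` resolves conflicts
deterministically: the longer span wins, ties fall to entity-type
precedence arthropod > trait > value > qualifier, and remaining ties to
the leftmost span. The output is overlap-free and independent of input
order.

## Normalisation

`normalize_entity()` links a surface to a concept id through ordered
tiers: exact → case-folded → whitespace-collapsed → plural-stripped
against preferred terms, then the synonym table. The first tier with a hit
wins; within-tier ambiguity resolves to the smallest concept id and is
flagged. Two summaries audit the result: the mapping summary (`m` entities
of a kind, `k` of them linked, percent mapped) and the coverage summary
(`n` dictionary concepts, `l` of them ever linked). Trait category
breakdowns are only possible after successful linking, since the tagger
itself only knows the coarse entity type. Percentages are reported to one
decimal by default with an integer-precision option, and coverage reports
always print `n` explicitly so the denominator is never ambiguous.

## Relations

The proximity baseline encodes how treatments are written: values sit next
to the traits they quantify (`hasValue` links each value to the nearest
preceding trait in its sentence — no trait in the sentence, no relation),
while taxa are mentioned once and described at length (`hasTrait` links
each trait to the nearest arthropod within the sentence window, preferring
preceding mentions; `hasQualifier` works like `hasValue`). Each tail
receives at most one head. The baseline over-predicts `hasTrait` by
design — it links every in-window trait — which is precisely the
behaviour a trained classifier should improve on; its recall against
nearest-mention truth is 1 by construction, which the tests exploit.

None-class balancing (`balance_none_class()`) down-samples `none`
candidates uniformly at random, seeded, to the size of the largest
positive class. Balancing is corpus-level, not per-document, matching the
purpose of limiting the negative class during training. Inline entity
tagging wraps the head in `<head type="...">` and the tail in
`<tail type="...">`; stripping the tags recovers the window text and both
spans exactly (property-tested, including adjacent entities).

## Evaluation, agreement, statistics

Two entity metrics are exposed because they answer different questions.
*Strict* scoring works on the annotation layer: a prediction counts only
if character span and type match gold exactly. *CoNLL-style* scoring works
on token chunks extracted from IOB2 with the lenient repair above. The two
coincide when predictions are well-formed and token-aligned — an
equivalence the test suite checks — and diverge exactly where boundary
granularity matters. Per-type precision/recall/F1 are aggregated as an
unweighted macro mean (macro-F is the mean of per-type F1 values, not the
harmonic mean of macro-P and macro-R, so reports stay internally
consistent) and a support-weighted mean. The zero-division convention is
P = R = F = 0 whenever a denominator is zero. Report rounding is two
decimals.

Inter-annotator agreement uses Cohen's kappa
`κ = (p_o − p_e) / (1 − p_e)` over units produced by greedy one-to-one
span alignment: pairs are admitted exactly (identical spans) or partially
(both boundary shifts within a per-boundary tolerance, default 4
characters) and matched in order of increasing combined boundary distance,
ties broken by earlier start then input order. Each matched pair is a unit
categorised by the two labels; each unmatched annotation is a unit against
the category "none". No synthetic true-negative mass is added — a
token-level contingency would require an arbitrary unit count — so kappa
values from this package are comparable with each other but not with
token-level kappas; this unitisation choice is the single largest lever on
the absolute numbers and is therefore stated prominently. Partial-mode
kappa is *not* guaranteed to exceed exact-mode kappa; what is guaranteed,
and tested, is that the matched-pair count is non-decreasing in the
tolerance. Fewer than two units is an error: kappa is undefined there.

Annotation densities are `1000 × count / length` per entity and relation
type. The corpus summary reports per-type totals, length quartiles
(linear-interpolation quantiles), per-split annotation totals and the
train/test percentage defined as `100 × train / test` over combined
entity-plus-relation counts — the convention that makes a small training
split comparable against a large evaluation split.

## The synthetic corpus generator

`generate_corpus()` exists so that every stage has an exact, offline
oracle. Documents are assembled from template sentences — species
introductions ("*Tipula oleracea* sp. nov. resembles its congeners."),
trait descriptions with colour or measurement values ("The femur measures
16.6 mm."), bare measurement series ("Segment ratios respectively 38, 47,
43."), qualifier mentions and entity-free fillers — with every planted
span recorded in the gold layer at its exact offset. Sentence types are
chosen deficit-first against per-type density targets, so realised
densities land within a few percent of the targets for documents of 2,000
characters and more (the tests assert ±20%).

Defaults are the annotation conditions of a manually curated treatment
corpus: densities 4.9 / 6.4 / 6.1 mentions per 1,000 characters for
arthropod / trait / value (plus 0.8 for qualifiers), 25 documents, and
relation structure in which traits link to the nearest preceding in-window
arthropod (few-to-many, long-range) while values link one-to-one to a
same-sentence trait. Document lengths default to 2,000–4,000 characters —
shorter than full published articles, sized so the whole suite runs in
seconds; the acceptance benchmark uses 50 documents at these lengths.
Noise rates (synonym variants, plurals, out-of-dictionary taxa) default to
zero, which yields the two by-construction guarantees the tests rely on:
the gazetteer + pattern taggers reproduce the gold entity layer exactly
(F1 = 1.0), and the proximity baseline recovers every planted relation
(recall = 1.0).

What the generator does *not* emulate: real linguistic variation (anaphora,
genus-initial abbreviations like "T. oleracea", discontinuous traits),
location values, the heavy-tailed length distribution of real articles,
and annotator disagreement. Passing the synthetic end-to-end tests
therefore demonstrates that the machinery is internally correct — offsets,
formats, metrics, determinism — not that the baselines would reach any
particular score on real treatments; on real corpora the published
experience is that dictionary normalisation covers taxa far better than
traits, and that RE is substantially harder than NER.

## Degenerate inputs and numerical conventions

Empty collections, empty dictionaries, empty entity layers and empty
corpora all return empty-but-well-typed objects rather than errors;
zero-length documents are an error for density computation (the quantity
is undefined). Seeded operations (`balance_none_class()`,
`generate_corpus()`) save and restore the caller's RNG state, so they are
reproducible without disturbing the session's random stream. All
percentages are computed before rounding; rounding happens only at the
report surface.

## Known limitations

* The gazetteer is both recogniser and normaliser; no reconciliation
  logic exists for a model tagger that disagrees with the dictionary.
* No location gazetteer, so place-name values are not tagged.
* No abbreviation expansion of genus initials; "T. oleracea" is guarded in
  sentence splitting but not linked to "Tipula oleracea".
* Kappa is two-annotator only; multi-annotator generalisations
  (Krippendorff's alpha) are out of scope.
* No confidence intervals or significance tests on evaluation reports.
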