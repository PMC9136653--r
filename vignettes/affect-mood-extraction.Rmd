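---
title: "Extracting clinician-recorded affect and mood: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting clinician-recorded affect and mood: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affectner)
```

## The extraction problem

Mental-health notes document a patient's affective presentation in two
registers: templated mental-status-exam fields (`Mood: ok`,
`Affect: constricted`) and free-text prose ("patient appeared sad even when
talking about his daughter's accomplishments").  `affectner` implements a
deliberately simple, fully deterministic pipeline for this setting:
a controlled vocabulary, dictionary named-entity recognition over
sentences, span-level agreement scoring between annotation sources,
third-coder adjudication, and corpus prevalence summaries.

Two concept classes are distinguished.  **AFFECT** covers valenced states
observed or expressed *during* the session: fleeting, context-dependent,
and potentially behavioral (crying), physiological (sweating) or
descriptive (blunted).  **MOOD** covers diffuse affective states whose
timeline extends beyond the session, usually patient-reported.  The
timeline criterion, not the word itself, separates the classes, which is
why several surface forms ("anxious", "irritable", "angry") legitimately
belong to both.

## The vocabulary

The bundled lexicon (`default_lexicon()`) compiles the descriptive,
behavioral and physiological characteristics of each class, plus
single-token descriptors recoverable from note excerpts ("tearful",
"anhedonia", "moody") and five comparative change markers ("improved",
"better", "less", "brighter", "broader").  Design choices:

* **No stemming or lemmatization.**  The matcher checks term and phrase
  occurrences; inflectional variants must be listed explicitly ("tearful"
  and "crying" are separate entries).  This keeps matching transparent and
  auditable — important when the vocabulary itself is the scientific
  instrument.
* **Shared surface forms are duplicated across classes**, not
  disambiguated in the lexicon.  Disambiguation is contextual, so it is
  the extractor's job (see the template override below).
* **Change markers carry no concept class.**  They are modifiers of
  affect descriptions ("his affect seems to be brighter"), not affective
  findings; the lexicon only tags them, and temporal analysis of change is
  out of scope.
* Each entry records its provenance in a `source` column so users can
  audit and extend the vocabulary by CSV.  The version notes record one
  known uncertainty: whether a deployed system's term list should equal
  the annotation-guideline vocabulary or be enlarged during error
  analysis; this lexicon is the guideline vocabulary.

## The matcher

`find_mentions()` segments a note and scans each sentence for lexicon
occurrences.  Matching parameters (all in `matcher_config()`, defaults in
parentheses):

* `case_sensitive` (off): matching is by normalized-form equality —
  lowercase, whitespace runs collapsed.
* `require_word_boundaries` (on): both match edges must sit at
  alphanumeric/non-alphanumeric transitions, so "flat" never matches
  inside "inflation".
* `longest_match_only` (on): an accepted match suppresses shorter
  candidates starting at covered positions *of the same concept class*
  ("less constricted" beats "constricted").  Suppression is per class so a
  MOOD match never shadows an AFFECT match: the two constructs are
  annotated independently.
* `template_field_override` (on): inside a sentence beginning `mood:`
  (case-insensitive) only MOOD mentions are kept; `affect:` keeps only
  AFFECT.  Dual-listed terms collapse to the field's class.

Sentence segmentation is rule-based: boundaries at `.`/`!`/`?` followed by
whitespace, and at every newline — templated fields routinely lack
terminal punctuation.  No statistical sentence model is used; determinism
matters more here than occasional abbreviation splits, and matches never
cross sentence boundaries.

Three behaviors are worth calling out because they differ from common
clinical-NLP defaults:

* **Negation is not filtering.**  "not tearful during the session today"
  yields a "tearful" AFFECT mention: a clinician noting the *absence* of
  tearfulness is still documenting session affect, and such negated
  phrasings are themselves canonical affect examples.  A NegEx-style layer
  would be a semantic change, not a bug fix.
* **Change markers are emitted only in context**: a CHANGE mention appears
  only when its sentence also contains a classed mention, and never when
  the marker lies inside an accepted classed span ("less" is not
  re-reported inside "less constricted").  Standalone "less" in arbitrary
  prose ("he slept less than usual") is noise, not affect.
* Internally the matcher scans the whole document once per lexicon entry
  and then discards candidates that cross sentence boundaries; this is
  equivalent to per-sentence scanning because sentence edges always sit at
  non-alphanumeric characters, and it is what makes corpus-scale
  extraction fast.

## Annotations and offsets

All standoff offsets are 0-based, half-open, and count Unicode code
points, never bytes — a note containing "patient’s" round-trips unchanged
through both dialects (eHOST-style XML, one file per document; and JSONL,
any number of documents).  Recorded surfaces in annotation files are
advisory: on read, surfaces are re-derived from the document text, and a
disagreement triggers a warning with the text slice winning.  Unknown XML
elements are ignored rather than rejected, since standoff schemas vary
across annotation-tool versions.

## Scoring, adjudication, and the error-analysis update

`match_spans()` pairs mentions one-to-one under a `match_policy()`:
`EXACT` (equal spans) or `OVERLAP` (spans sharing at least one character),
optionally requiring equal concept class (default on).  The package
default is `OVERLAP`: human annotators and a dictionary system rarely
agree on exact boundaries of multi-word affect descriptions, and
overlap-based agreement is the stricter-to-game, looser-to-pass convention
most span-annotation studies report.  `EXACT` is available for strictness
studies.

The pairing is a true **maximum** one-to-one matching, computed by
augmenting paths seeded from a greedy pass in deterministic
(start, longest-first) order.  A pure greedy pairing by earliest
start/longest span is *not* always maximum under `OVERLAP` (two nested
spans on one side against two disjoint ones on the other can strand a
pair), and a metric built on a non-maximum matching would undercount
agreement, so the maximum-matching property is treated as the defining
invariant; the greedy order merely fixes which maximum matching is
returned.  The tests verify equality with an exhaustive matching oracle on
random instances.

Counts follow the usual convention — TP = pairs, FP = unmatched in the
predicted set, FN = unmatched in the gold set — and
`F = 2PR/(P + R)` on the 0–100 scale.  Interannotator agreement,
system accuracy, and "overall accuracy" are all this F-measure; "overall"
is the micro-F pooled across classes and is labeled as such in every
report.  Undefined ratios (empty denominator) are flagged `NA` rather than
silently zeroed; F is 0 when exactly one side is empty and `NA` when both
are.  Mentions without a concept class (CHANGE markers) never enter
scoring, which is defined per concept class.

`adjudicate()` implements third-coder adjudication: agreed mentions enter
the reference set directly (annotator A's span by convention — the spans
are identical under `EXACT` and the choice is then immaterial), and every
disagreement must carry exactly one KEEP/REJECT verdict; coverage
mismatches are hard errors listing the offending keys, because a silent
default on either side would bias the reference.

`error_analysis_update()` implements post-hoc validation of system
findings: each system false positive judged valid joins the reference set
and is recounted as a true positive; the rest remain false positives.
Since the update only ever adds reference mentions that the system found,
precision and recall are non-decreasing — a property the suite checks on
random fixtures.

Printed percentages round half-up to one decimal (62.65 prints as 62.7,
matching clinical reporting style); internal values keep full precision.

## Prevalence summaries

`flag_notes()` reduces mentions to per-note booleans; `prevalence()` and
`share_among_positive()` produce stratified rates with half-up rounding at
one decimal.  Missing stratum labels are pooled under `"unknown"` rather
than dropped so denominators always equal the full corpus.  Note-level
rates depend only on the flags, so they can be computed from any
annotation source (an annotator, the system, or a reference set).

## The synthetic generator

Real clinical notes cannot be distributed, so `generate()` produces
synthetic ones for end-to-end testing.  Each note mixes templated
`Mood:`/`Affect:` lines, free-text sentences embedding one vocabulary
phrase each, and distractor sentences (plans, medication lines) built to
contain no lexicon surface form.  Defaults are the package's study
conditions: affect documented in 87.8% of notes and mood in 97.3% (the
documentation rates reported for outpatient mental-health corpora), a
psychology/psychiatry provider mix of 64/83, the matching note-type mix,
and an even split between templated and free-text placement — the last is
a package choice, since published sources say only that both registers are
frequent.

Determinism is structural: one substream per note, keyed by the master
seed and the note index, so growing `n_notes` never reshuffles earlier
notes.  `oov_rate` replaces a gold mention's surface with an
out-of-lexicon paraphrase; the paraphrase pool is disjoint from the
bundled lexicon by construction (a test extracts over every pool phrase
and requires zero matches), so recall degrades as `100·(1 − oov_rate)`
in expectation while precision stays at 100%.

Two generator constraints keep the zero-noise recovery invariant exact
(extraction F = 100% for both classes): free-text slots draw only
surfaces listed under exactly one concept class, because a dual-listed
surface in free text legitimately yields one mention per class and would
need double gold; and dual-listed surfaces appear only in templated
fields, where the field label fixes the class for gold and extractor
alike.

What the generator does **not** emulate — and therefore what passing
tests cannot show about real notes: misspellings and typos, abbreviation
noise ("pt tearful @ times"), paraphrases beyond the fixed pool,
section headers other than the two template cues, copy-forward
boilerplate, and any correlation between note type and language.  Results
on synthetic corpora bound the pipeline's mechanical correctness, not its
real-world recall, which is limited by vocabulary coverage.

## Scales used in the test suite

The matcher is checked against a brute-force substring oracle on 1,000
random fixtures (documents ≤ 500 characters, lexicons ≤ 50 entries);
standoff round-trips on 500 random annotation sets across both dialects;
agreement properties and the maximum-matching oracle on random instances
with up to 10 mentions per document; recovery and noise response on
200-note synthetic corpora.  These sizes were chosen to exercise every
code path several hundred times while keeping the default suite fast
enough to run on every change.

## Known limitations

* Dictionary matching cannot find what the vocabulary does not list; the
  lexicon is the instrument, and coverage work is ongoing.
* The CHANGE category is tagged but not attached to the mention it
  modifies; longitudinal change analysis is explicitly out of scope.
* No chance-corrected agreement (kappa/alpha) is computed — the reference
  workflow reports span-level F only.
* Sentence segmentation will split clinical abbreviations ("Dr. Smith");
  in templated notes this is harmless, in narrative prose it can shorten
  sentences and with them the reach of the template override (never the
  matches themselves, which respect the finer segmentation on both sides
  of the scoring).
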