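# affectner

Clinicians routinely record a patient's observable **affect** (the valenced
state expressed during a session — "affect is constricted and at times
tearful") and self-reported **mood** (the diffuse state spanning days or
weeks — "mood has remained somewhat depressed") in mental-health notes.
These observations track the course of depression more closely than billing
codes or symptom questionnaires, but they live in free text and templated
mental-status-exam fields, out of reach of structured analysis.

`affectner` is an R toolkit for extracting and evaluating this information:

* a bundled **controlled vocabulary** of affect/mood characteristics —
  descriptive (blunted, flat, euthymic, ...), behavioral (crying, laughing,
  smiling), physiological (sweating, rapid respiration) and comparative
  **change markers** (improved, better, less, ...) — extensible via CSV;
* a rule-based **dictionary NER extractor**: sentence segmentation tuned to
  clinical notes (newlines and terminal punctuation), word-boundary-aware
  longest-match phrase lookup, one mention per concept class for ambiguous
  terms ("anxious" is both an affect and a mood descriptor), and a
  template override so `Mood:`/`Affect:` fields disambiguate their contents;
* **standoff annotation I/O** in an eHOST-style XML dialect and a JSONL
  dialect, with character-offset validation against the source text;
* **double-annotation scoring**: span matching (exact or overlap), agreement
  as the span-level F-measure
  `F = 2PR/(P+R)` with `P = TP/(TP+FP)`, `R = TP/(TP+FN)`,
  third-coder **adjudication** into a reference set, and the
  **error-analysis update rule** — a system finding judged valid post hoc
  joins the reference set and is recounted as a true positive;
* **prevalence reporting**: per-note concept flags and stratified
  documentation rates by note type and provider type;
* a deterministic **synthetic note generator** with gold annotations,
  configurable concept prevalence and out-of-vocabulary noise, used to
  exercise the full pipeline end to end.

## Worked example

```r
library(affectner)
lex <- default_lexicon()
note <- corpus("note1",
  "Mood: depressed\nAffect: constricted and at times tearful. Pt was anxious when discussing sleep.\nPlan: continue current regimen.")
mentions <- find_mentions(note, lex)
as.data.frame(mentions[, c("start", "end", "concept_class", "category", "surface")])
#>   start end concept_class    category     surface
#> 1     6  15          MOOD DESCRIPTIVE   depressed
#> 2    24  35        AFFECT DESCRIPTIVE constricted
#> 3    49  56        AFFECT DESCRIPTIVE     tearful
#> 4    65  72        AFFECT DESCRIPTIVE     anxious
#> 5    65  72          MOOD DESCRIPTIVE     anxious
```

The templated `Mood:` field forces its content to the MOOD class, while the
free-text "anxious" — listed under both constructs in the vocabulary — is
emitted once per class.  Offsets are 0-based, half-open, code-point offsets
into the verbatim note text.

Scoring a system against a reference set (here, the same mentions with one
deleted from the system side):

```r
ref <- mentions; ref$source <- "reference"
sys <- mentions[-2, ]                 # system missed "constricted"
evaluate_system(sys, ref)
#> class        TP     FP     FN  precision   recall        F
#> AFFECT        2      0      1      100.0     66.7     80.0
#> MOOD          2      0      0      100.0    100.0    100.0
#> overall       4      0      1      100.0     80.0     88.9
```

A shell entry point mirrors the annotate → adjudicate → extract → evaluate →
summarize workflow:

```sh
Rscript exec/affectner synth   --n 200 --seed 9 --out synth/
Rscript exec/affectner extract --corpus synth/corpus.jsonl --out system.jsonl
Rscript exec/affectner eval    --corpus synth/corpus.jsonl \
    --system system.jsonl --reference synth/gold.jsonl --out eval
```

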