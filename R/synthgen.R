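#' Synthetic corpus configuration
#'
#' Study conditions for the synthetic mental-health note generator.  The
#' defaults emulate the documentation rates and note mix observed in
#' outpatient mental-health corpora: affect documented in about 87.8% of
#' notes and mood in about 97.3%, note types distributed as in typical
#' mental-health note tables (consults, medication management, psychology
#' and psychiatry notes), and a psychology/psychiatry provider split of
#' 64/83.  Concept mentions are placed in templated mental-status-exam
#' fields ("Mood: ...", "Affect: ...") or in free-text sentences.
#'
#' @param n_notes number of notes to generate.
#' @param affect_prevalence probability a note documents affect.
#' @param mood_prevalence probability a note documents mood.
#' @param oov_rate probability a gold mention is realized with an
#'   out-of-lexicon paraphrase (irrecoverable by dictionary matching).
#' @param templated_fraction share of concept mentions placed in templated
#'   fields rather than free text.
#' @param seed master seed; per-note substreams are derived from it by
#'   note index, so earlier notes are unchanged when `n_notes` grows.
#' @param note_type_weights,provider_type_weights,setting_weights named
#'   nonnegative weights summing to 1 (tolerance 1e-9).
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_notes = 100,
                         affect_prevalence = 0.878,
                         mood_prevalence = 0.973,
                         oov_rate = 0,
                         templated_fraction = 0.5,
                         seed = 1,
                         note_type_weights = c(
                           "Mental health consult" = 16 / 147,
                           "Mental health note" = 38 / 147,
                           "Mental health outpatient note" = 5 / 147,
                           "Psychiatry medication management" = 33 / 147,
                           "Psychiatry note" = 27 / 147,
                           "Psychology note" = 11 / 147,
                           "Other types" = 17 / 147),
                         provider_type_weights = c(
                           psychology = 64 / 147, psychiatry = 83 / 147),
                         setting_weights = c(
                           specialty = 119 / 147, primary_care = 28 / 147)) {
  probs <- c(affect_prevalence, mood_prevalence, oov_rate, templated_fraction)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    abort_validation("prevalences, oov_rate and templated_fraction must lie in [0,1]")
  }
  for (w in list(note_type_weights, provider_type_weights, setting_weights)) {
    if (any(w < 0) || abs(sum(w) - 1) > 1e-9 || is.null(names(w))) {
      abort_validation("weights must be named, nonnegative, and sum to 1")
    }
  }
  if (n_notes < 1) abort_validation("n_notes must be positive")
  structure(list(n_notes = as.integer(n_notes),
                 affect_prevalence = affect_prevalence,
                 mood_prevalence = mood_prevalence,
                 oov_rate = oov_rate,
                 templated_fraction = templated_fraction,
                 seed = as.integer(seed),
                 note_type_weights = note_type_weights,
                 provider_type_weights = provider_type_weights,
                 setting_weights = setting_weights),
            class = "synth_config")
}

#' Out-of-lexicon paraphrase pool
#'
#' Affect/mood phrasings a clinician might write that are absent from the
#' bundled controlled vocabulary, used by the generator to realize
#' out-of-vocabulary gold mentions.  Disjoint from the default lexicon by
#' construction: no normalized pool phrase (or any token sequence inside
#' one) matches a default-lexicon surface form.
#'
#' @return character vector of paraphrases.
#' @export
paraphrase_pool <- function() {
  c("despondent", "glum", "morose", "weepy", "subdued", "downcast",
    "keyed up", "on edge", "emotionally distant", "wrung out",
    "seemed emotionally shut down", "inwardly troubled")
}

# Sentence frames for free-text mentions; frame tokens are disjoint from
# lexicon surface forms so the only system match in such a sentence is the
# embedded term.  %s marks the term slot.
affect_frames <- c(
  "Patient appeared %s during the session.",
  "On examination the patient was %s at times.",
  "They were noted to be %s when discussing recent events.")
mood_frames <- c(
  "Patient reports feeling %s for several weeks.",
  "Over the past month they have been %s most days.",
  "Reports being %s since the previous visit.")
distractor_lines <- c(
  "Medication reconciliation completed.",
  "Plan: continue current regimen and follow up in four weeks.",
  "Patient attended the appointment on time.",
  "Sleep hygiene and coping skills were reviewed.",
  "No changes to the treatment plan.")

# Build one note; returns list(text=, gold=tibble rows with offsets).
build_note <- function(doc_id, cfg, lex) {
  aff_entries <- lex[!is.na(lex$concept_class) & lex$concept_class == "AFFECT", ]
  moo_entries <- lex[!is.na(lex$concept_class) & lex$concept_class == "MOOD", ]
  dual <- intersect(aff_entries$surface_form, moo_entries$surface_form)
  aff_free <- aff_entries[!aff_entries$surface_form %in% dual, ]
  moo_free <- moo_entries[!moo_entries$surface_form %in% dual, ]

  has_affect <- stats::runif(1) < cfg$affect_prevalence
  has_mood <- stats::runif(1) < cfg$mood_prevalence

  plan <- list()
  add_concept <- function(cls, entries_any, entries_free, frames, field) {
    n_m <- sample(1:2, 1, prob = c(0.7, 0.3))
    for (k in seq_len(n_m)) {
      templated <- stats::runif(1) < cfg$templated_fraction
      pool <- if (templated) entries_any else entries_free
      entry <- pool[sample(nrow(pool), 1), ]
      oov <- stats::runif(1) < cfg$oov_rate
      surface <- if (oov) sample(paraphrase_pool(), 1) else entry$surface_form
      line <- if (templated) paste0(field, ": ", surface)
              else sprintf(sample(frames, 1), surface)
      plan[[length(plan) + 1L]] <<- list(
        line = line, surface = surface, cls = cls,
        category = if (oov) NA_character_ else entry$category, oov = oov)
    }
  }
  if (has_affect && nrow(aff_entries) > 0) {
    add_concept("AFFECT", aff_entries, aff_free, affect_frames, "Affect")
  }
  if (has_mood && nrow(moo_entries) > 0) {
    add_concept("MOOD", moo_entries, moo_free, mood_frames, "Mood")
  }
  n_distract <- sample(1:3, 1)
  for (k in seq_len(n_distract)) {
    plan[[length(plan) + 1L]] <- list(line = sample(distractor_lines, 1),
                                      surface = NA, cls = NA, category = NA,
                                      oov = FALSE)
  }
  plan <- plan[sample(length(plan))]

  lines <- vapply(plan, function(p) p$line, character(1))
  text <- paste(lines, collapse = "\n")
  offset <- 0L
  gold <- list()
  for (p in plan) {
    if (!is.na(p$cls)) {
      pos <- regexpr(p$surface, p$line, fixed = TRUE)
      start <- offset + as.integer(pos) - 1L
      gold[[length(gold) + 1L]] <- tibble::tibble(
        doc_id = doc_id, start = start,
        end = start + nchar(p$surface),
        concept_class = p$cls, category = as.character(p$category),
        surface = p$surface, oov = p$oov)
    }
    offset <- offset + nchar(p$line) + 1L  # + newline
  }
  list(text = text,
       gold = if (length(gold) == 0) NULL else do.call(rbind, gold),
       has_affect = has_affect, has_mood = has_mood)
}

#' Generate a synthetic annotated corpus
#'
#' Produces mental-health-style notes mixing templated mental-status-exam
#' fields, free-text sentences embedding vocabulary phrases, and
#' distractor sentences free of lexicon terms, together with
#' gold-standard annotations.  Deterministic given `(cfg, lex)`: the same
#' seed yields a byte-identical corpus, and per-note substreams keyed by
#' note index keep earlier notes stable when `n_notes` changes.  With
#' `oov_rate = 0` every gold surface is a lexicon surface form; with
#' `oov_rate = q` each gold mention is independently realized as an
#' out-of-lexicon paraphrase with probability `q` (category is then
#' unknown).
#'
#' @param cfg a [synth_config()].
#' @param lex the generating lexicon (defaults to [default_lexicon()]).
#' @return a `synth_corpus` list: `documents` (corpus tibble), `gold`
#'   (annotation tibble, source `"gold"`), `manifest` (config plus
#'   realized counts).
#' @export
generate <- function(cfg = synth_config(), lex = default_lexicon()) {
  stopifnot(inherits(cfg, "synth_config"))
  if ((cfg$affect_prevalence > 0 || cfg$mood_prevalence > 0) && nrow(lex) == 0) {
    abort_validation("nonzero prevalence requires a nonempty lexicon")
  }
  docs <- list(); golds <- list()
  n_aff <- 0L; n_moo <- 0L
  for (i in seq_len(cfg$n_notes)) {
    doc_id <- sprintf("note%04d", i)
    note <- with_rng(derive_seed(cfg$seed, i), {
      meta <- list(
        note_type = sample(names(cfg$note_type_weights), 1,
                           prob = cfg$note_type_weights),
        provider_type = sample(names(cfg$provider_type_weights), 1,
                               prob = cfg$provider_type_weights),
        setting = sample(names(cfg$setting_weights), 1,
                         prob = cfg$setting_weights))
      c(build_note(doc_id, cfg, lex), meta)
    })
    docs[[i]] <- tibble::tibble(doc_id = doc_id, text = note$text,
                                note_type = note$note_type,
                                provider_type = note$provider_type,
                                setting = note$setting)
    if (!is.null(note$gold)) golds[[length(golds) + 1L]] <- note$gold
    if (note$has_affect) n_aff <- n_aff + 1L
    if (note$has_mood) n_moo <- n_moo + 1L
  }
  documents <- do.call(rbind, docs)
  goldraw <- if (length(golds) == 0) NULL else do.call(rbind, golds)
  gold <- if (is.null(goldraw)) annotation_set(source = "gold")
          else annotation_set(goldraw$doc_id, goldraw$start, goldraw$end,
                              goldraw$concept_class, goldraw$category,
                              goldraw$surface, source = "gold")
  gold <- validate_annotations(gold, documents)
  manifest <- list(
    config = unclass(cfg),
    realized = list(
      n_notes = cfg$n_notes,
      notes_with_affect = n_aff,
      notes_with_mood = n_moo,
      gold_mentions = nrow(gold),
      oov_mentions = if (is.null(goldraw)) 0L else sum(goldraw$oov)))
  structure(list(documents = documents, gold = gold, manifest = manifest),
            class = "synth_corpus")
}

#' Write a synthetic corpus to disk
#'
#' Emits `corpus.jsonl`, `gold.jsonl` and `manifest.yaml` into `dir`.
#'
#' @param sc a `synth_corpus` from [generate()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth_corpus <- function(sc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_corpus(sc$documents, file.path(dir, "corpus.jsonl"))
  write_annotations(sc$gold, file.path(dir, "gold.jsonl"), dialect = "jsonl")
  yaml::write_yaml(sc$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
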