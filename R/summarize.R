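#' Note-level concept presence flags
#'
#' Reduces mention-level annotations to per-note booleans: `has_affect`
#' (at least one AFFECT mention) and `has_mood` (at least one MOOD
#' mention), carrying the note metadata along for stratified prevalence.
#'
#' @param docs a corpus tibble.
#' @param anns one annotation tibble (or a list of them, concatenated).
#' @return a tibble with one row per document: `doc_id`, `has_affect`,
#'   `has_mood`, `note_type`, `provider_type`, `setting`.
#' @export
flag_notes <- function(docs, anns) {
  if (is.list(anns) && !is.data.frame(anns)) anns <- do.call(rbind, anns)
  if (is.null(anns)) anns <- annotation_set()
  orphan <- setdiff(unique(anns$doc_id), docs$doc_id)
  if (length(orphan) > 0) {
    abort_data(paste0("annotations refer to unknown doc_id(s): ",
                      paste(orphan, collapse = ", ")))
  }
  aff <- unique(anns$doc_id[!is.na(anns$concept_class) &
                              anns$concept_class == "AFFECT"])
  moo <- unique(anns$doc_id[!is.na(anns$concept_class) &
                              anns$concept_class == "MOOD"])
  tibble::tibble(
    doc_id = docs$doc_id,
    has_affect = docs$doc_id %in% aff,
    has_mood = docs$doc_id %in% moo,
    note_type = if ("note_type" %in% names(docs)) docs$note_type else NA_character_,
    provider_type = if ("provider_type" %in% names(docs)) docs$provider_type else NA_character_,
    setting = if ("setting" %in% names(docs)) docs$setting else NA_character_
  )
}

prevalence_table <- function(stratum, numerator, denominator) {
  tibble::tibble(
    stratum = as.character(stratum),
    numerator = as.integer(numerator),
    denominator = as.integer(denominator),
    percentage = round_half_up(100 * numerator / denominator, 1)
  )
}

strata_of <- function(flags, stratify_by) {
  s <- flags[[stratify_by]]
  ifelse(is.na(s) | s == "", "unknown", s)
}

#' Concept documentation prevalence
#'
#' Fraction of notes documenting a concept, overall or stratified.
#' Per-stratum: numerator = concept-positive notes in the stratum,
#' denominator = notes in the stratum.  Notes with missing stratum labels
#' are collected under `"unknown"` so denominators always total the full
#' corpus.  Percentages are rounded half-up to one decimal.
#'
#' @param flags a [flag_notes()] tibble.
#' @param stratify_by `"none"`, `"note_type"`, or `"provider_type"`.
#' @param concept `"AFFECT"` or `"MOOD"`.
#' @return a prevalence tibble: `stratum`, `numerator`, `denominator`,
#'   `percentage`.
#' @export
prevalence <- function(flags, stratify_by = c("none", "note_type", "provider_type"),
                       concept = c("AFFECT", "MOOD")) {
  stratify_by <- match.arg(stratify_by)
  concept <- match.arg(concept)
  if (nrow(flags) == 0) return(prevalence_table(character(0), integer(0), integer(0)))
  pos <- if (concept == "AFFECT") flags$has_affect else flags$has_mood
  if (stratify_by == "none") {
    return(prevalence_table("all notes", sum(pos), nrow(flags)))
  }
  s <- strata_of(flags, stratify_by)
  labs <- sort(unique(s))
  prevalence_table(labs,
                   vapply(labs, function(l) sum(pos & s == l), integer(1)),
                   vapply(labs, function(l) sum(s == l), integer(1)))
}

#' Stratum shares among concept-positive notes
#'
#' Among the notes documenting the concept, what share falls in each
#' stratum: the denominator is the count of concept-positive notes and
#' the numerators are concept-positive notes per stratum, so percentages
#' sum to 100 up to rounding.
#'
#' @inheritParams prevalence
#' @return a prevalence tibble (empty if no note is concept-positive).
#' @export
share_among_positive <- function(flags, stratify_by = "provider_type",
                                 concept = c("AFFECT", "MOOD")) {
  concept <- match.arg(concept)
  pos <- if (concept == "AFFECT") flags$has_affect else flags$has_mood
  total <- sum(pos)
  if (length(total) == 0 || total == 0) {
    return(prevalence_table(character(0), integer(0), integer(0)))
  }
  s <- strata_of(flags, stratify_by)
  labs <- sort(unique(s[pos]))
  prevalence_table(labs,
                   vapply(labs, function(l) sum(pos & s == l), integer(1)),
                   rep(total, length(labs)))
}

#' Corpus composition by note type
#'
#' Count and percentage of the corpus per note type; denominators equal
#' the corpus size, so a fully labeled partition's numerators sum to it.
#'
#' @param docs a corpus tibble.
#' @return a prevalence tibble.
#' @export
note_type_table <- function(docs) {
  if (nrow(docs) == 0) return(prevalence_table(character(0), integer(0), integer(0)))
  s <- ifelse(is.na(docs$note_type) | docs$note_type == "", "unknown",
              docs$note_type)
  labs <- sort(unique(s))
  prevalence_table(labs,
                   vapply(labs, function(l) sum(s == l), integer(1)),
                   rep(nrow(docs), length(labs)))
}

#' Write a prevalence table as CSV or aligned text
#'
#' @param tab a prevalence tibble.
#' @param path output path.
#' @param format `"csv"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_prevalence <- function(tab, path, format = c("csv", "text")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(as.data.frame(tab), path, row.names = FALSE,
                     fileEncoding = "UTF-8")
  } else {
    lines <- c(sprintf("%-40s %10s %12s %8s", "stratum", "n", "of", "pct"),
               sprintf("%-40s %10d %12d %8.1f", tab$stratum, tab$numerator,
                       tab$denominator, tab$percentage))
    writeLines(lines, path, useBytes = FALSE)
  }
  invisible(path)
}
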