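#' Concept classes and term categories
#'
#' The controlled vocabulary distinguishes two concept classes:
#' `AFFECT` (valenced states observed or expressed during the clinical
#' session — fleeting, context-dependent) and `MOOD` (diffuse affective
#' states spanning days to weeks, usually patient-reported).  Every lexicon
#' entry and every mention carries exactly one class, except
#' comparative-change markers, which carry no class of their own.
#'
#' Term categories describe how a characteristic manifests in a note:
#' `DESCRIPTIVE` (e.g. "blunted", "euthymic"), `BEHAVIORAL` (e.g. "crying"),
#' `PHYSIOLOGICAL` (e.g. "sweating"), and `CHANGE` — comparative adjectives
#' such as "improved" or "less" that signal change relative to a prior
#' session.  `CHANGE` is a modifier category only: its entries never carry a
#' concept class.
#'
#' @format Character vectors of the valid labels.
#' @name concept-classes
NULL

#' @rdname concept-classes
#' @export
CONCEPT_CLASSES <- c("AFFECT", "MOOD")

#' @rdname concept-classes
#' @export
TERM_CATEGORIES <- c("DESCRIPTIVE", "BEHAVIORAL", "PHYSIOLOGICAL", "CHANGE")

#' Normalize a vocabulary term or candidate match
#'
#' Lowercases, collapses internal whitespace runs to single spaces, strips
#' surrounding whitespace and terminal punctuation.  Idempotent; empty input
#' yields empty output.  This is the normal form under which all lexicon
#' lookup and matching equality is defined.
#'
#' @param raw character vector of raw terms.
#' @return character vector of normalized terms.
#' @examples
#' normalize_term("  Blunted, ")        # "blunted"
#' normalize_term("Rapid Respiration")  # "rapid respiration"
#' @export
normalize_term <- function(raw) {
  if (length(raw) == 0) return(character(0))
  x <- tolower(as.character(raw))
  x <- gsub("[[:space:]]+", " ", x)
  x <- sub("^ +", "", x)
  x <- sub(" +$", "", x)
  # terminal punctuation (possibly repeated, possibly followed by nothing)
  x <- sub("[.,;:!?]+$", "", x)
  x <- sub(" +$", "", x)
  x
}

new_lexicon <- function(entries, name = "lexicon", version = "0") {
  entries <- tibble::as_tibble(entries)
  structure(entries, class = c("affect_lexicon", class(entries)),
            lexicon_name = name, lexicon_version = version)
}

#' Validate a lexicon
#'
#' Checks the structural invariants: required columns; non-empty normalized
#' surface forms; classes in `AFFECT`/`MOOD` (or `NA` for CHANGE markers
#' only); categories among the four term categories; uniqueness of
#' (surface_form, concept_class) pairs.
#'
#' @param lex a lexicon tibble as returned by [load_lexicon()].
#' @return the lexicon, invisibly, if valid; otherwise an error.
#' @export
validate_lexicon <- function(lex) {
  needed <- c("surface_form", "concept_class", "category", "source")
  miss <- setdiff(needed, names(lex))
  if (length(miss) > 0) {
    abort_validation(paste0("lexicon is missing column(s): ",
                            paste(miss, collapse = ", ")))
  }
  sf <- lex$surface_form
  if (any(is.na(sf) | sf == "")) {
    abort_validation("lexicon contains empty surface forms")
  }
  if (any(sf != normalize_term(sf))) {
    bad <- sf[sf != normalize_term(sf)][1]
    abort_validation(paste0("surface form not in normal form: '", bad, "'"))
  }
  cc <- lex$concept_class
  bad_class <- !is.na(cc) & !(cc %in% CONCEPT_CLASSES)
  if (any(bad_class)) {
    abort_validation(paste0("invalid concept class '", cc[bad_class][1],
                            "' at row ", which(bad_class)[1]))
  }
  cat_bad <- !(lex$category %in% TERM_CATEGORIES)
  if (any(cat_bad)) {
    abort_validation(paste0("invalid category '", lex$category[cat_bad][1],
                            "' at row ", which(cat_bad)[1]))
  }
  # CHANGE entries never carry a class; classed entries are never CHANGE
  chg <- lex$category == "CHANGE"
  if (any(chg & !is.na(cc))) {
    abort_validation("CHANGE entries must not carry a concept class")
  }
  if (any(!chg & is.na(cc))) {
    abort_validation("non-CHANGE entries must carry a concept class")
  }
  key <- paste(sf, ifelse(is.na(cc), "", cc))
  if (anyDuplicated(key)) {
    abort_validation(paste0("duplicate (surface_form, concept_class): ",
                            key[duplicated(key)][1]))
  }
  invisible(lex)
}

#' Load a lexicon from CSV
#'
#' The CSV dialect is UTF-8, comma-separated, RFC 4180 quoting, with a
#' header row `term,class,category` (an optional `source` column is carried
#' through).  Surface forms are normalized on load; duplicate
#' (surface_form, class) rows collapse to one with a warning.  An empty
#' `class` field is valid only for `CHANGE` rows.
#'
#' @param path path to a lexicon CSV file.
#' @param name,version metadata attached to the lexicon.
#' @return a lexicon tibble with columns `surface_form`, `concept_class`,
#'   `category`, `source`.
#' @export
load_lexicon <- function(path, name = basename(path), version = "0") {
  if (!file.exists(path)) {
    abort_validation(paste0("lexicon file not found: ", path))
  }
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  for (col in c("term", "class", "category")) {
    if (!col %in% names(raw)) {
      abort_validation(paste0("lexicon CSV is missing required column '",
                              col, "'"))
    }
  }
  if (!"source" %in% names(raw)) raw$source <- rep("", nrow(raw))
  if (nrow(raw) == 0) {
    return(new_lexicon(tibble::tibble(surface_form = character(0),
                                      concept_class = character(0),
                                      category = character(0),
                                      source = character(0)),
                       name = name, version = version))
  }
  cls <- toupper(trimws(raw$class))
  bad <- which(!(cls %in% c(CONCEPT_CLASSES, "")))
  if (length(bad) > 0) {
    abort_validation(paste0("row ", bad[1], ": class '", raw$class[bad[1]],
                            "' is not AFFECT, MOOD, or empty"))
  }
  cat <- toupper(trimws(raw$category))
  badc <- which(!(cat %in% TERM_CATEGORIES))
  if (length(badc) > 0) {
    abort_validation(paste0("row ", badc[1], ": category '",
                            raw$category[badc[1]],
                            "' is not one of ",
                            paste(TERM_CATEGORIES, collapse = "/")))
  }
  lex <- tibble::tibble(
    surface_form = normalize_term(raw$term),
    concept_class = ifelse(cls == "", NA_character_, cls),
    category = cat,
    source = raw$source
  )
  key <- paste(lex$surface_form,
               ifelse(is.na(lex$concept_class), "", lex$concept_class))
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    warning(paste0("collapsing duplicate lexicon rows: ",
                   paste(dups, collapse = "; ")), call. = FALSE)
    lex <- lex[!duplicated(key), ]
  }
  lex <- new_lexicon(lex, name = name, version = version)
  validate_lexicon(lex)
  lex
}

#' Save a lexicon to CSV
#'
#' Inverse of [load_lexicon()]: `load_lexicon(save_lexicon(lex, p))`
#' reproduces an equal entry set.
#'
#' @param lex a lexicon.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
save_lexicon <- function(lex, path) {
  out <- data.frame(
    term = lex$surface_form,
    class = ifelse(is.na(lex$concept_class), "", lex$concept_class),
    category = lex$category,
    source = lex$source,
    check.names = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' The bundled affect/mood controlled vocabulary
#'
#' Returns the packaged core lexicon of clinician-recorded affect and mood
#' characteristics: 24 AFFECT descriptive terms (e.g. "blunted", "flat",
#' "constricted", "within normal limits"), 3 behavioral ("crying",
#' "laughing", "smiling"), 2 physiological ("sweating", "rapid
#' respiration"), the MOOD descriptive terms ("depressed", "low",
#' "dysphoric", "anxious", "irritable", "euphoric", "angry"), a handful of
#' single-token descriptors recoverable from note excerpts (e.g. "tearful",
#' "anhedonia", "moody"), and the comparative change markers ("improved",
#' "better", "less", "brighter", "broader").
#'
#' Some surface forms ("anxious", "irritable", "angry") are deliberately
#' listed under both AFFECT and MOOD; disambiguation is the extractor's
#' concern (see [apply_template_override()]).  The version notes record
#' that the published vocabulary source does not distinguish the
#' annotation-guideline vocabulary from any system term list enlarged
#' during error analysis; this lexicon is the guideline vocabulary.
#'
#' @return a lexicon tibble (see [load_lexicon()]).
#' @examples
#' lex <- default_lexicon()
#' lexicon_lookup(lex, "euthymic")
#' @export
default_lexicon <- function() {
  path <- system.file("extdata", "affect_mood_lexicon.csv",
                      package = "affectner", mustWork = TRUE)
  load_lexicon(path, name = "affect-mood-core",
               version = "1.0 (guideline vocabulary; system-list uncertainty documented)")
}

#' Look up a term in a lexicon
#'
#' Normalizes the query and returns all matching entries across classes
#' (a surface form listed under both AFFECT and MOOD returns two rows).
#'
#' @param lex a lexicon.
#' @param term raw term text (normalized internally).
#' @return the matching lexicon rows (possibly zero).
#' @export
lexicon_lookup <- function(lex, term) {
  q <- normalize_term(term)
  lex[lex$surface_form == q, , drop = FALSE]
}
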