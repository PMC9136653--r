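#' Matcher configuration
#'
#' Controls the dictionary matcher.  The defaults are the reference
#' behavior used throughout the package's tests: case-insensitive,
#' word-boundary-aware, longest-match-per-class, with templated
#' mental-status-exam fields ("Mood:", "Affect:") overriding concept class.
#'
#' @param case_sensitive match surface forms case-sensitively.
#' @param require_word_boundaries require alphanumeric/non-alphanumeric
#'   transitions at both match edges ("flat" never matches inside
#'   "inflation").
#' @param longest_match_only an accepted match suppresses shorter
#'   candidates starting at covered positions, per concept class (a MOOD
#'   match never suppresses an AFFECT match).
#' @param template_field_override apply [apply_template_override()] after
#'   matching.
#' @return a `matcher_config` list.
#' @export
matcher_config <- function(case_sensitive = FALSE,
                           require_word_boundaries = TRUE,
                           longest_match_only = TRUE,
                           template_field_override = TRUE) {
  structure(list(case_sensitive = isTRUE(case_sensitive),
                 require_word_boundaries = isTRUE(require_word_boundaries),
                 longest_match_only = isTRUE(longest_match_only),
                 template_field_override = isTRUE(template_field_override)),
            class = "matcher_config")
}

#' Segment a note into sentences
#'
#' Rule-based segmentation suited to clinical notes, which mix free-text
#' prose with templated fields that often lack terminal punctuation:
#' boundaries fall after sentence-terminal punctuation (`.` `!` `?`)
#' followed by whitespace, and at every newline.  Segments are trimmed of
#' surrounding whitespace; empty segments are dropped.  Returned spans are
#' 0-based half-open offsets into the document text, non-overlapping and
#' ordered.
#'
#' @param doc a one-row corpus slice (or any list with `doc_id` and `text`).
#' @return a tibble with columns `doc_id`, `start`, `end`, `text`.
#' @export
segment_sentences <- function(doc) {
  text <- doc$text[[1]]
  doc_id <- doc$doc_id[[1]]
  empty <- tibble::tibble(doc_id = character(0), start = integer(0),
                          end = integer(0), text = character(0))
  n <- nchar(text)
  if (is.na(text) || n == 0) return(empty)
  # candidate break positions: position AFTER which a new segment starts
  breaks <- integer(0)
  m <- gregexpr("[.!?]+[[:space:]]", text)[[1]]
  if (m[1] != -1) {
    # break after the punctuation run, before the whitespace
    breaks <- c(breaks, as.integer(m) + attr(m, "match.length") - 1L - 1L)
  }
  nl <- gregexpr("\n", text, fixed = TRUE)[[1]]
  if (nl[1] != -1) breaks <- c(breaks, as.integer(nl) - 1L)  # 0-based, before \n
  breaks <- sort(unique(breaks))
  starts0 <- c(0L, breaks + 1L)
  ends0 <- c(breaks + 1L, n)
  keep <- starts0 < ends0
  starts0 <- starts0[keep]; ends0 <- ends0[keep]
  segs <- substring(text, starts0 + 1, ends0)
  lead <- nchar(segs) - nchar(sub("^[[:space:]]+", "", segs))
  trail <- nchar(segs) - nchar(sub("[[:space:]]+$", "", segs))
  s <- as.integer(starts0 + lead)
  e <- as.integer(ends0 - trail)
  keep <- s < e
  s <- s[keep]; e <- e[keep]
  if (length(s) == 0) return(empty)
  tibble::tibble(doc_id = doc_id, start = s, end = e,
                 text = substring(text, s + 1, e))
}

# Build a regex for one surface form: tokens (split on spaces) escaped and
# rejoined with \s+, with alphanumeric boundary guards.
surface_regex <- function(surface, boundaries = TRUE) {
  toks <- strsplit(surface, " ", fixed = TRUE)[[1]]
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", toks)
  core <- paste(esc, collapse = "[[:space:]]+")
  if (boundaries) paste0("(?<![[:alnum:]])", core, "(?![[:alnum:]])")
  else core
}

#' Find lexicon mentions in one document
#'
#' The core named-entity-recognition step: the note is segmented into
#' sentences, and each sentence is scanned left to right for occurrences
#' of lexicon surface forms.  A candidate is an occurrence whose
#' normalized form equals a lexicon surface form, respecting word
#' boundaries; matches never cross sentence boundaries.  Under
#' `longest_match_only`, an accepted match suppresses shorter candidates
#' starting at covered positions of the same concept class.  A surface
#' form listed under both AFFECT and MOOD yields one mention per class.
#'
#' Comparative change markers (category CHANGE, no class) are emitted only
#' when the same sentence also contains a classed mention, and never when
#' the marker lies inside an accepted classed span (so "less" is not
#' re-reported inside "less constricted").  Negated contexts are matched,
#' not suppressed: "not tearful during the session today" yields a
#' "tearful" AFFECT mention, because negated phrasings are themselves
#' valid affect documentation in clinical notes.
#'
#' @param doc a one-row corpus slice.
#' @param lex a lexicon (see [load_lexicon()]).
#' @param cfg a [matcher_config()].
#' @return an annotation tibble with source `"system"`.
#' @export
find_mentions <- function(doc, lex, cfg = matcher_config()) {
  text <- doc$text[[1]]
  sents <- segment_sentences(doc)
  if (nrow(sents) == 0 || nrow(lex) == 0) {
    return(annotation_set(source = "system"))
  }
  scan <- if (cfg$case_sensitive) text else tolower(text)
  # one whole-document scan per lexicon entry; candidates crossing sentence
  # boundaries are discarded below, which reproduces per-sentence matching
  # because sentence edges always sit at non-alphanumeric characters
  cs <- integer(0); ce <- integer(0); cls <- character(0); cat <- character(0)
  for (li in seq_len(nrow(lex))) {
    rx <- surface_regex(lex$surface_form[li],
                        boundaries = cfg$require_word_boundaries)
    m <- gregexpr(rx, scan, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    s0 <- as.integer(m) - 1L
    cs <- c(cs, s0)
    ce <- c(ce, s0 + attr(m, "match.length"))
    cls <- c(cls, rep(lex$concept_class[li], length(s0)))
    cat <- c(cat, rep(lex$category[li], length(s0)))
  }
  if (length(cs) == 0) return(annotation_set(source = "system"))
  si <- findInterval(cs, sents$start)
  ok <- si >= 1L & cs >= sents$start[pmax(si, 1L)] & ce <= sents$end[pmax(si, 1L)]
  cs <- cs[ok]; ce <- ce[ok]; cls <- cls[ok]; cat <- cat[ok]; si <- si[ok]
  if (length(cs) == 0) return(annotation_set(source = "system"))
  keep <- resolve_candidates(si, cs, ce, cls, cfg)
  cs <- cs[keep]; ce <- ce[keep]; cls <- cls[keep]; cat <- cat[keep]; si <- si[keep]
  if (cfg$template_field_override && length(cs) > 0) {
    stext <- tolower(sents$text)
    only <- ifelse(startsWith(stext, "mood:"), "MOOD",
                   ifelse(startsWith(stext, "affect:"), "AFFECT",
                          NA_character_))
    drop <- !is.na(only[si]) & !is.na(cls) & cls != only[si]
    cs <- cs[!drop]; ce <- ce[!drop]; cls <- cls[!drop]; cat <- cat[!drop]
  }
  if (length(cs) == 0) return(annotation_set(source = "system"))
  annotation_set(doc$doc_id[[1]], cs, ce, cls, cat,
                 surface = substring(text, cs + 1, ce), source = "system")
}

# Longest-match resolution per (sentence, concept class), plus the CHANGE
# co-occurrence rule; returns a logical keep mask over the candidates.
resolve_candidates <- function(si, cs, ce, cls, cfg) {
  n <- length(cs)
  keep <- logical(n)
  classed <- which(!is.na(cls))
  ord <- classed[order(si[classed], cls[classed], cs[classed],
                       -(ce[classed] - cs[classed]), method = "radix")]
  group <- ""
  covered_to <- -1L
  for (i in ord) {
    g <- paste0(si[i], "\r", cls[i])
    if (g != group) { group <- g; covered_to <- -1L }
    if (!cfg$longest_match_only) {
      keep[i] <- TRUE
    } else if (cs[i] > covered_to) {
      keep[i] <- TRUE
      covered_to <- ce[i] - 1L
    }
  }
  if (!cfg$longest_match_only && length(classed) > 0) {
    dup <- duplicated(paste(si, cs, ce, cls)) & !is.na(cls)
    keep[dup] <- FALSE
  }
  # CHANGE markers: only alongside a kept classed mention in the same
  # sentence, and never inside a kept classed span
  change <- which(is.na(cls))
  if (length(change) > 0) {
    kept_classed <- which(keep & !is.na(cls))
    seen <- character(0)
    for (i in change) {
      here <- kept_classed[si[kept_classed] == si[i]]
      if (length(here) == 0) next
      if (any(cs[i] >= cs[here] & ce[i] <= ce[here])) next
      key <- paste(cs[i], ce[i])
      if (key %in% seen) next
      seen <- c(seen, key)
      keep[i] <- TRUE
    }
  }
  keep
}

#' Apply the templated-field class override
#'
#' Mental-status-exam templates label concepts explicitly: within a
#' sentence whose text begins (case-insensitively) with `"mood:"`, only
#' MOOD-class mentions are kept; within one beginning `"affect:"`, only
#' AFFECT.  Dual-class duplicates collapse to the field's class; mentions
#' outside templated fields are unchanged.  CHANGE-marker mentions (no
#' class) are never dropped by the override.
#'
#' @param mentions an annotation tibble for `doc`.
#' @param doc the one-row corpus slice the mentions refer to.
#' @return the filtered annotation tibble.
#' @export
apply_template_override <- function(mentions, doc) {
  if (nrow(mentions) == 0) return(mentions)
  sents <- segment_sentences(doc)
  drop <- logical(nrow(mentions))
  for (si in seq_len(nrow(sents))) {
    stext <- tolower(sents$text[si])
    only <- if (startsWith(stext, "mood:")) "MOOD"
            else if (startsWith(stext, "affect:")) "AFFECT"
            else next
    in_sent <- mentions$start >= sents$start[si] & mentions$end <= sents$end[si]
    drop <- drop | (in_sent & !is.na(mentions$concept_class) &
                      mentions$concept_class != only)
  }
  mentions[!drop, , drop = FALSE]
}

#' Extract mentions over a whole corpus
#'
#' Runs [find_mentions()] on every document.  Deterministic: identical
#' inputs produce identical output.
#'
#' @param docs a corpus tibble.
#' @param lex a lexicon.
#' @param cfg a [matcher_config()].
#' @return a single annotation tibble (source `"system"`) covering all
#'   documents.
#' @export
extract_corpus <- function(docs, lex, cfg = matcher_config()) {
  sets <- lapply(seq_len(nrow(docs)), function(i) {
    find_mentions(docs[i, , drop = FALSE], lex, cfg)
  })
  if (length(sets) == 0) return(annotation_set(source = "system"))
  do.call(rbind, sets)
}
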