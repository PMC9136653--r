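#' Build an annotation set
#'
#' An annotation set holds all mentions produced by one source (an
#' annotator id, `"system"`, `"reference"`, or `"gold"`) as a tibble with
#' columns `doc_id`, `start`, `end` (0-based, half-open, code-point
#' offsets), `concept_class` (`AFFECT`/`MOOD`, or `NA` for CHANGE-marker
#' mentions), `category` (optional), `surface`, `source`.
#'
#' @param doc_id,start,end,concept_class,category,surface per-mention
#'   vectors (recycled where scalar).
#' @param source single source label applied to all mentions.
#' @return an annotation tibble.
#' @export
annotation_set <- function(doc_id = character(0), start = integer(0),
                           end = integer(0), concept_class = character(0),
                           category = NA_character_, surface = NA_character_,
                           source = "unknown") {
  n <- max(length(doc_id), length(start))
  ann <- tibble::tibble(
    doc_id = rep_len(as.character(doc_id), n),
    start = as.integer(start),
    end = as.integer(end),
    concept_class = rep_len(as.character(concept_class), n),
    category = rep_len(as.character(category), n),
    surface = rep_len(as.character(surface), n),
    source = rep_len(as.character(source), n)
  )
  ann[order(ann$doc_id, ann$start, ann$end, ann$concept_class,
            method = "radix"), , drop = FALSE]
}

#' Validate mentions against their documents
#'
#' Enforces the mention invariants: offsets within the document text
#' (`0 <= start < end <= nchar(text)`), classes in `AFFECT`/`MOOD` (or `NA`
#' with category `CHANGE`), one source label per set, and no duplicate
#' (doc_id, start, end, concept_class).  Surfaces are re-derived from the
#' document text; a recorded surface that disagrees triggers a warning and
#' the re-derived slice wins.
#'
#' @param ann an annotation tibble.
#' @param docs the corpus the annotations refer to.
#' @return the validated annotation tibble with authoritative surfaces.
#' @export
validate_annotations <- function(ann, docs) {
  if (nrow(ann) == 0) return(ann)
  if (length(unique(ann$source)) > 1) {
    abort_validation("annotation set mixes source labels")
  }
  bad_class <- !is.na(ann$concept_class) &
    !(ann$concept_class %in% CONCEPT_CLASSES)
  if (any(bad_class)) {
    abort_validation(paste0("mention ", which(bad_class)[1],
                            ": class '", ann$concept_class[bad_class][1],
                            "' is not AFFECT or MOOD"))
  }
  key <- paste(ann$doc_id, ann$start, ann$end, ann$concept_class)
  if (anyDuplicated(key)) {
    abort_validation(paste0("duplicate mention (doc_id,start,end,class): ",
                            key[duplicated(key)][1]))
  }
  for (i in seq_len(nrow(ann))) {
    doc <- get_document(docs, ann$doc_id[i])
    len <- nchar(doc$text)
    if (is.na(ann$start[i]) || is.na(ann$end[i]) ||
        ann$start[i] < 0 || ann$start[i] >= ann$end[i] || ann$end[i] > len) {
      abort_data(paste0("mention ", i, " (doc ", ann$doc_id[i],
                        "): span [", ann$start[i], ",", ann$end[i],
                        ") outside document of length ", len))
    }
    derived <- slice_text(doc$text, ann$start[i], ann$end[i])
    if (!is.na(ann$surface[i]) && ann$surface[i] != derived) {
      warning(paste0("mention ", i, " (doc ", ann$doc_id[i],
                     "): recorded surface '", ann$surface[i],
                     "' disagrees with text slice '", derived,
                     "'; using the slice"), call. = FALSE)
    }
    ann$surface[i] <- derived
  }
  ann
}

# ---- JSONL standoff dialect ------------------------------------------------

read_annotations_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(annotation_set())
  recs <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) abort_data(
                      paste0("line ", i, ": invalid JSON annotation record")))
    for (k in c("doc_id", "start", "end")) {
      if (is.null(rec[[k]])) {
        abort_data(paste0("line ", i, ": annotation missing '", k, "'"))
      }
    }
    opt <- function(k) if (is.null(rec[[k]])) NA_character_ else as.character(rec[[k]])
    tibble::tibble(doc_id = as.character(rec$doc_id),
                   start = as.integer(rec$start), end = as.integer(rec$end),
                   concept_class = opt("concept_class"),
                   category = opt("category"),
                   surface = opt("surface"),
                   source = if (is.null(rec$source)) "unknown" else as.character(rec$source))
  })
  do.call(rbind, recs)
}

write_annotations_jsonl <- function(ann, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(ann))) {
    rec <- list(doc_id = ann$doc_id[i], start = ann$start[i],
                end = ann$end[i])
    if (!is.na(ann$concept_class[i])) rec$concept_class <- ann$concept_class[i]
    if (!is.na(ann$category[i])) rec$category <- ann$category[i]
    if (!is.na(ann$surface[i])) rec$surface <- ann$surface[i]
    rec$source <- ann$source[i]
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

# ---- eHOST-style XML dialect ----------------------------------------------
# One file per document: <annotations textSource="doc_id"> containing, per
# mention, an <annotation> (with <mention id/>, <annotator>, <span
# start end/>, <spannedText>) and a matching <classMention id> whose
# <mentionClass id> carries AFFECT/MOOD (or the CHANGE category for
# unclassed change-marker mentions).  Unknown elements are ignored.

read_annotations_xml <- function(path) {
  doc <- xml2::read_xml(path)
  doc_id <- xml2::xml_attr(doc, "textSource")
  anns <- xml2::xml_find_all(doc, ".//annotation")
  cms <- xml2::xml_find_all(doc, ".//classMention")
  cm_ids <- vapply(cms, function(cm) xml2::xml_attr(cm, "id"), character(1))
  cls_by_id <- stats::setNames(
    vapply(cms, function(cm) {
      mc <- xml2::xml_find_first(cm, "./mentionClass")
      xml2::xml_attr(mc, "id")
    }, character(1)), cm_ids)
  cat_by_id <- stats::setNames(
    vapply(cms, function(cm) {
      mc <- xml2::xml_find_first(cm, "./mentionClass")
      xml2::xml_attr(mc, "category")
    }, character(1)), cm_ids)
  if (length(anns) == 0) return(annotation_set())
  recs <- lapply(seq_along(anns), function(i) {
    a <- anns[[i]]
    sp <- xml2::xml_find_first(a, "./span")
    if (is.na(sp)) abort_data(paste0("annotation ", i, ": missing span"))
    mid <- xml2::xml_attr(xml2::xml_find_first(a, "./mention"), "id")
    label <- if (!is.na(mid) && mid %in% names(cls_by_id)) cls_by_id[[mid]] else NA_character_
    concept <- if (!is.na(label) && label %in% CONCEPT_CLASSES) label else NA_character_
    category <- if (!is.na(mid) && mid %in% names(cat_by_id)) cat_by_id[[mid]] else NA_character_
    if (is.na(category) && !is.na(label) && label %in% TERM_CATEGORIES &&
        is.na(concept)) {
      category <- label
    }
    annotator <- xml2::xml_text(xml2::xml_find_first(a, "./annotator"))
    surface <- xml2::xml_text(xml2::xml_find_first(a, "./spannedText"))
    tibble::tibble(doc_id = doc_id,
                   start = as.integer(xml2::xml_attr(sp, "start")),
                   end = as.integer(xml2::xml_attr(sp, "end")),
                   concept_class = concept,
                   category = category,
                   surface = if (is.na(surface)) NA_character_ else surface,
                   source = if (is.na(annotator) || annotator == "") "unknown" else annotator)
  })
  do.call(rbind, recs)
}

write_annotations_xml <- function(ann, path) {
  if (nrow(ann) > 0 && length(unique(ann$doc_id)) > 1) {
    abort_validation("the XML dialect holds one document per file")
  }
  doc_id <- if (nrow(ann) > 0) ann$doc_id[1] else ""
  root <- xml2::xml_new_root("annotations", textSource = doc_id)
  for (i in seq_len(nrow(ann))) {
    mid <- paste0("Instance_", i)
    a <- xml2::xml_add_child(root, "annotation")
    xml2::xml_add_child(a, "mention", id = mid)
    xml2::xml_add_child(a, "annotator", ann$source[i])
    xml2::xml_add_child(a, "span", start = as.character(ann$start[i]),
                        end = as.character(ann$end[i]))
    if (!is.na(ann$surface[i])) {
      xml2::xml_add_child(a, "spannedText", ann$surface[i])
    }
    label <- if (!is.na(ann$concept_class[i])) ann$concept_class[i]
             else if (!is.na(ann$category[i])) ann$category[i]
             else NA_character_
    if (!is.na(label)) {
      cm <- xml2::xml_add_child(root, "classMention", id = mid)
      if (!is.na(ann$concept_class[i]) && !is.na(ann$category[i])) {
        xml2::xml_add_child(cm, "mentionClass", id = label,
                            category = ann$category[i])
      } else {
        xml2::xml_add_child(cm, "mentionClass", id = label)
      }
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

#' Read standoff annotations
#'
#' Autodetects the dialect (eHOST-style XML vs JSONL) from the file
#' content.  Mentions are validated against `docs` and surfaces re-derived
#' from the document text (the file's recorded surface is advisory only).
#'
#' @param path annotation file.
#' @param docs the corpus the annotations refer to.
#' @param source optional source label override (defaults to the label(s)
#'   recorded in the file).
#' @return a validated annotation tibble.
#' @export
read_annotations <- function(path, docs, source = NULL) {
  if (!file.exists(path)) {
    abort_validation(paste0("annotation file not found: ", path))
  }
  first <- readLines(path, n = 1, warn = FALSE)
  ann <- if (length(first) > 0 && grepl("^\\s*<", first[1])) {
    read_annotations_xml(path)
  } else {
    read_annotations_jsonl(path)
  }
  if (!is.null(source)) ann$source <- source
  ann <- annotation_set(ann$doc_id, ann$start, ann$end, ann$concept_class,
                        ann$category, ann$surface,
                        source = if (nrow(ann) > 0) ann$source else "unknown")
  validate_annotations(ann, docs)
}

#' Write standoff annotations
#'
#' Writes either dialect; `read_annotations()` on the result reproduces an
#' equal mention set (offsets are code-point offsets and survive non-ASCII
#' text under UTF-8).
#'
#' @param ann an annotation tibble.
#' @param path output file.
#' @param dialect `"jsonl"` (any number of documents) or `"xml"`
#'   (one document per file).
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path, dialect = c("jsonl", "xml")) {
  dialect <- match.arg(dialect)
  if (dialect == "jsonl") write_annotations_jsonl(ann, path)
  else write_annotations_xml(ann, path)
  invisible(path)
}
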