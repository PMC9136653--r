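#' Build a document corpus
#'
#' A corpus is a tibble with one row per note: `doc_id`, verbatim `text`,
#' and optional metadata `note_type` (e.g. "Mental health consult",
#' "Psychiatry medication management"), `provider_type` ("psychology",
#' "psychiatry", or other) and `setting` ("specialty", "primary_care", or
#' other).  Text is stored verbatim — normalization happens only inside
#' matching — and `doc_id` must be unique.
#'
#' @param doc_id character vector of unique document ids.
#' @param text character vector of note texts.
#' @param note_type,provider_type,setting optional metadata vectors.
#' @return a corpus tibble sorted by `doc_id`.
#' @export
corpus <- function(doc_id, text, note_type = NA_character_,
                   provider_type = NA_character_, setting = NA_character_) {
  docs <- tibble::tibble(
    doc_id = as.character(doc_id),
    text = as.character(text),
    note_type = rep_len(as.character(note_type), length(doc_id)),
    provider_type = rep_len(as.character(provider_type), length(doc_id)),
    setting = rep_len(as.character(setting), length(doc_id))
  )
  validate_corpus(docs)
  docs[order(docs$doc_id), , drop = FALSE]
}

validate_corpus <- function(docs) {
  for (col in c("doc_id", "text")) {
    if (!col %in% names(docs)) {
      abort_validation(paste0("corpus is missing column '", col, "'"))
    }
  }
  if (anyDuplicated(docs$doc_id)) {
    abort_data(paste0("duplicate doc_id in corpus: ",
                      paste(unique(docs$doc_id[duplicated(docs$doc_id)]),
                            collapse = ", ")))
  }
  if (any(is.na(docs$text))) {
    abort_data("corpus contains records with missing text")
  }
  invisible(docs)
}

#' Read a corpus from a directory of text files or a JSONL file
#'
#' A directory is read as one UTF-8 `.txt` file per note (the file stem
#' becomes `doc_id`).  A JSONL file has one object per line with keys
#' `doc_id`, `text`, and optionally `note_type`, `provider_type`,
#' `setting`.  Documents are returned in lexicographic `doc_id` order.
#'
#' @param path directory or JSONL file path.
#' @return a corpus tibble.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) {
    abort_validation(paste0("corpus path not found: ", path))
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    texts <- vapply(files, function(f) {
      paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n")
    }, character(1))
    return(corpus(doc_id = sub("\\.txt$", "", basename(files)), text = texts))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) abort_data(
                      paste0("line ", i, ": invalid JSON record")))
    if (is.null(rec$doc_id) || is.null(rec$text)) {
      abort_data(paste0("line ", i, ": record missing doc_id or text"))
    }
    grab <- function(k) {
      v <- rec[[k]]
      if (is.null(v) || length(v) == 0 || is.na(v[1])) NA_character_
      else as.character(v[1])
    }
    tibble::tibble(doc_id = as.character(rec$doc_id),
                   text = as.character(rec$text),
                   note_type = grab("note_type"),
                   provider_type = grab("provider_type"),
                   setting = grab("setting"))
  })
  docs <- do.call(rbind, recs)
  if (is.null(docs)) {
    docs <- tibble::tibble(doc_id = character(0), text = character(0),
                           note_type = character(0),
                           provider_type = character(0),
                           setting = character(0))
  }
  validate_corpus(docs)
  docs[order(docs$doc_id), , drop = FALSE]
}

#' Write a corpus as JSONL
#'
#' @param docs a corpus tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(docs, path) {
  validate_corpus(docs)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(docs))) {
    rec <- list(doc_id = docs$doc_id[i], text = docs$text[i])
    for (k in c("note_type", "provider_type", "setting")) {
      if (k %in% names(docs) && !is.na(docs[[k]][i])) rec[[k]] <- docs[[k]][i]
    }
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

# Fetch one document row by id; errors if absent.
get_document <- function(docs, doc_id) {
  i <- which(docs$doc_id == doc_id)
  if (length(i) != 1) {
    abort_data(paste0("doc_id not found in corpus: ", doc_id))
  }
  docs[i, , drop = FALSE]
}
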