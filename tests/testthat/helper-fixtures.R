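# Shared fixtures and independent oracles for the test suite.
# The matcher oracle and the matching oracle are deliberately written as
# naive, loop-based re-derivations, independent of the package's code paths.

tiny_lexicon <- function(rows) {
  # rows: list of c(term, class_or_NA, category)
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  if (length(rows) == 0) {
    writeLines("term,class,category", path)
  } else {
    tb <- do.call(rbind, lapply(rows, function(r) {
      tibble::tibble(surface_form = r[[1]],
                     concept_class = if (is.na(r[[2]])) NA_character_ else r[[2]],
                     category = r[[3]])
    }))
    utils::write.csv(
      data.frame(term = tb$surface_form,
                 class = ifelse(is.na(tb$concept_class), "", tb$concept_class),
                 category = tb$category),
      path, row.names = FALSE)
  }
  load_lexicon(path, name = "tiny")
}

one_doc <- function(text, doc_id = "d1") corpus(doc_id, text)

# ---- independent sentence segmentation (character scan) --------------------

oracle_sentences <- function(text) {
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  if (n == 0) return(data.frame(start = integer(0), end = integer(0)))
  is_p <- chars %in% c(".", "!", "?")
  is_ws <- grepl("[[:space:]]", chars)
  brk <- rep(FALSE, n)  # TRUE at i: a new segment starts at i+1 (0-based i+1)
  for (i in seq_len(n - 1)) {
    if (is_p[i] && !is_p[i + 1] && is_ws[i + 1]) brk[i] <- TRUE
    if (chars[i + 1] == "\n") brk[i] <- TRUE  # segment ends before the \n
    if (chars[i] == "\n") brk[i] <- TRUE      # and resumes after it
  }
  bounds <- c(0, which(brk), n)  # 0-based segment edges
  out <- list()
  for (k in seq_len(length(bounds) - 1)) {
    s <- bounds[k]; e <- bounds[k + 1]
    while (s < e && is_ws[s + 1]) s <- s + 1
    while (e > s && is_ws[e]) e <- e - 1
    if (s < e) out[[length(out) + 1]] <- data.frame(start = s, end = e)
  }
  if (length(out) == 0) return(data.frame(start = integer(0), end = integer(0)))
  do.call(rbind, out)
}

# ---- brute-force matcher oracle -------------------------------------------
# Assumes fixture documents use single spaces inside sentences, so a match's
# length equals its surface form's length.  Scans every start position of
# every sentence for every entry, filters by alphanumeric word boundaries,
# then applies longest-match per class, the CHANGE co-occurrence rule, and
# the template override.

oracle_find_mentions <- function(text, lex) {
  sents <- oracle_sentences(text)
  low <- tolower(text)
  is_alnum <- function(ch) grepl("[[:alnum:]]", ch)
  chars <- strsplit(low, "")[[1]]
  cands <- list()
  for (si in seq_len(nrow(sents))) {
    s0 <- sents$start[si]; e0 <- sents$end[si]
    stext <- substring(low, s0 + 1, e0)
    for (li in seq_len(nrow(lex))) {
      surf <- lex$surface_form[li]
      L <- nchar(surf)
      if (L > nchar(stext)) next
      starts <- seq_len(nchar(stext) - L + 1)
      hits <- starts[substring(stext, starts, starts + L - 1) == surf]
      for (h in hits) {
        g0 <- s0 + h - 1  # 0-based doc offset
        before_ok <- g0 == 0 || !is_alnum(chars[g0])
        after_ok <- g0 + L >= nchar(text) || !is_alnum(chars[g0 + L + 1])
        if (before_ok && after_ok) {
          cands[[length(cands) + 1]] <- data.frame(
            sent = si, start = g0, end = g0 + L,
            concept_class = lex$concept_class[li],
            category = lex$category[li], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(cands) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      concept_class = character(0), category = character(0)))
  }
  cands <- do.call(rbind, cands)
  kept <- list()
  for (si in unique(cands$sent)) {
    sc <- cands[cands$sent == si, ]
    classed <- sc[!is.na(sc$concept_class), ]
    acc <- classed[0, ]
    for (cls in unique(classed$concept_class)) {
      cc <- classed[classed$concept_class == cls, ]
      cc <- cc[order(cc$start, -(cc$end - cc$start)), ]
      covered <- -1
      for (i in seq_len(nrow(cc))) {
        if (cc$start[i] > covered) {
          acc <- rbind(acc, cc[i, ])
          covered <- cc$end[i] - 1
        }
      }
    }
    ch <- sc[is.na(sc$concept_class), ]
    if (nrow(ch) > 0 && nrow(acc) > 0) {
      ok <- vapply(seq_len(nrow(ch)), function(i) {
        !any(ch$start[i] >= acc$start & ch$end[i] <= acc$end)
      }, logical(1))
      ch <- ch[ok, ]
      ch <- ch[!duplicated(paste(ch$start, ch$end)), ]
      acc <- rbind(acc, ch)
    }
    # template override
    stext <- tolower(substring(text, sents$start[si] + 1, sents$end[si]))
    only <- if (startsWith(stext, "mood:")) "MOOD"
            else if (startsWith(stext, "affect:")) "AFFECT" else NA
    if (!is.na(only) && nrow(acc) > 0) {
      acc <- acc[is.na(acc$concept_class) | acc$concept_class == only, ]
    }
    if (nrow(acc) > 0) kept[[length(kept) + 1]] <- acc
  }
  if (length(kept) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      concept_class = character(0), category = character(0)))
  }
  out <- do.call(rbind, kept)
  out[order(out$start, out$end, out$concept_class), c("start", "end", "concept_class", "category")]
}

mention_sig <- function(df) {
  if (nrow(df) == 0) return(character(0))
  sort(paste(df$start, df$end,
             ifelse(is.na(df$concept_class), "-", df$concept_class),
             ifelse(is.na(df$category), "-", df$category)))
}

# ---- random fixtures -------------------------------------------------------

rand_word <- function(n = 1) {
  vapply(seq_len(n), function(i) {
    paste(sample(letters, sample(3:8, 1), replace = TRUE), collapse = "")
  }, character(1))
}

# A random lexicon of <= max_entries, with some multi-word phrases, some
# dual-class surfaces, and a couple of CHANGE markers.
rand_lexicon <- function(max_entries = 50) {
  n <- sample(5:max_entries, 1)
  words <- rand_word(max(10, n))
  surfaces <- unique(vapply(seq_len(n), function(i) {
    k <- sample(1:3, 1, prob = c(0.6, 0.3, 0.1))
    paste(sample(words, k, replace = FALSE), collapse = " ")
  }, character(1)))
  rows <- list()
  for (s in surfaces) {
    r <- stats::runif(1)
    if (r < 0.1) {
      rows[[length(rows) + 1]] <- list(s, NA, "CHANGE")
    } else if (r < 0.25) {
      rows[[length(rows) + 1]] <- list(s, "AFFECT", "DESCRIPTIVE")
      rows[[length(rows) + 1]] <- list(s, "MOOD", "DESCRIPTIVE")
    } else if (r < 0.6) {
      rows[[length(rows) + 1]] <- list(s, "AFFECT",
                                       sample(c("DESCRIPTIVE", "BEHAVIORAL",
                                                "PHYSIOLOGICAL"), 1))
    } else {
      rows[[length(rows) + 1]] <- list(s, "MOOD", "DESCRIPTIVE")
    }
  }
  tb <- do.call(rbind, lapply(rows, function(r) {
    tibble::tibble(surface_form = r[[1]],
                   concept_class = if (is.na(r[[2]])) NA_character_ else r[[2]],
                   category = r[[3]], source = "random")
  }))
  affectner:::new_lexicon(tb, name = "random")
}

# A random document <= max_chars built from lexicon tokens, whole surfaces,
# and unrelated words; single-spaced tokens; sentence breaks via ". " and
# newlines; occasional templated "Mood:"/"Affect:" lines.
rand_document <- function(lex, max_chars = 500) {
  toks <- unique(unlist(strsplit(lex$surface_form, " ")))
  other <- rand_word(8)
  pieces <- character(0)
  repeat {
    r <- stats::runif(1)
    piece <- if (r < 0.35) sample(lex$surface_form, 1)
             else if (r < 0.7) sample(toks, 1)
             else sample(other, 1)
    if (stats::runif(1) < 0.12) {
      prefix <- sample(c("Mood:", "Affect:"), 1)
      piece <- paste(prefix, piece)
      pieces <- c(pieces, paste0("\n", piece, "\n"))
    } else {
      sep <- sample(c(" ", " ", " ", ". ", "! ", "? ", "\n"), 1)
      pieces <- c(pieces, paste0(piece, sep))
    }
    text <- paste(pieces, collapse = "")
    if (nchar(text) > max_chars * 0.8) break
  }
  text <- substr(paste(pieces, collapse = ""), 1, max_chars)
  gsub("[ ]+", " ", text)
}

# Random valid annotation set over a corpus of given documents.
rand_annotations <- function(docs, source = "annA", max_per_doc = 6) {
  rows <- list()
  for (i in seq_len(nrow(docs))) {
    len <- nchar(docs$text[i])
    if (len < 2) next
    n <- sample(0:max_per_doc, 1)
    seen <- character(0)
    for (k in seq_len(n)) {
      s <- sample(0:(len - 1), 1)
      e <- min(len, s + sample(1:10, 1))
      cls <- sample(c("AFFECT", "MOOD"), 1)
      key <- paste(s, e, cls)
      if (key %in% seen) next
      seen <- c(seen, key)
      rows[[length(rows) + 1]] <- tibble::tibble(
        doc_id = docs$doc_id[i], start = s, end = e, concept_class = cls,
        category = sample(c(NA, "DESCRIPTIVE"), 1))
    }
  }
  if (length(rows) == 0) return(annotation_set(source = source))
  df <- do.call(rbind, rows)
  annotation_set(df$doc_id, df$start, df$end, df$concept_class, df$category,
                 NA_character_, source = source)
}

# Exhaustive maximum one-to-one matching size (bitmask DP over b, memoized).
oracle_max_matching <- function(a, b, policy) {
  a <- a[!is.na(a$concept_class), ]
  b <- b[!is.na(b$concept_class), ]
  na <- nrow(a); nb <- nrow(b)
  compat <- function(i, j) {
    if (a$doc_id[i] != b$doc_id[j]) return(FALSE)
    if (policy$class_must_match &&
        a$concept_class[i] != b$concept_class[j]) return(FALSE)
    if (policy$mode == "EXACT") a$start[i] == b$start[j] && a$end[i] == b$end[j]
    else a$start[i] < b$end[j] && b$start[j] < a$end[i]
  }
  memo <- new.env(parent = emptyenv())
  best <- function(i, mask) {
    if (i > na) return(0)
    key <- paste(i, mask)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    res <- best(i + 1, mask)  # leave a[i] unmatched
    for (j in seq_len(nb)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) == 0 && compat(i, j)) {
        res <- max(res, 1 + best(i + 1, bitwOr(mask, bit)))
      }
    }
    memo[[key]] <- res
    res
  }
  best(1, 0L)
}

# Re-expresses an annotation tibble as the list-of-spans form used by
# test constructors (to duplicate a set under a different source label).
a_to_list <- function(ann) {
  lapply(seq_len(nrow(ann)), function(i) {
    c(ann$doc_id[i], ann$start[i], ann$end[i], ann$concept_class[i])
  })
}

# Binomial 95% acceptance band for an observed count.
binom_band <- function(n, p) {
  c(stats::qbinom(0.025, n, p), stats::qbinom(0.975, n, p))
}
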