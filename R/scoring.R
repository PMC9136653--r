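#' Span-matching policy
#'
#' Defines when two mentions from different sources count as the same
#' finding.  `EXACT` requires equal spans; `OVERLAP` requires the spans to
#' share at least one character position.  With `class_must_match` (the
#' default) the concept classes must also agree.  The package default is
#' `OVERLAP` + class match: annotators and a dictionary system rarely agree
#' on the exact boundaries of phrases such as "tightly controlled, comes
#' across as somewhat blunted"; `EXACT` is provided for strictness studies.
#'
#' @param mode `"OVERLAP"` or `"EXACT"`.
#' @param class_must_match require equal concept class for a pair.
#' @return a `match_policy` list.
#' @export
match_policy <- function(mode = c("OVERLAP", "EXACT"), class_must_match = TRUE) {
  mode <- match.arg(toupper(mode[1]), c("OVERLAP", "EXACT"))
  structure(list(mode = mode, class_must_match = isTRUE(class_must_match)),
            class = "match_policy")
}

# Only classed mentions take part in scoring; CHANGE markers carry no
# concept class and are modifiers, not findings.
classed_only <- function(ann) {
  ann[!is.na(ann$concept_class), , drop = FALSE]
}

pair_compatible <- function(a, i, b, j, policy) {
  if (a$doc_id[i] != b$doc_id[j]) return(FALSE)
  if (policy$class_must_match &&
      !identical(a$concept_class[i], b$concept_class[j])) return(FALSE)
  if (policy$mode == "EXACT") {
    a$start[i] == b$start[j] && a$end[i] == b$end[j]
  } else {
    a$start[i] < b$end[j] && b$start[j] < a$end[i]
  }
}

#' Match spans between two annotation sets
#'
#' Computes a maximum one-to-one pairing between the mentions of `a` and
#' `b` under the policy.  Mentions are processed greedily in deterministic
#' (doc_id, start, longest-span-first) order and the initial greedy pairing
#' is then improved by augmenting paths, so the result is a true maximum
#' matching (the greedy order fixes which pairing is returned among
#' maximum ones).  Each mention participates in at most one pair.
#' Unclassed CHANGE-marker mentions are excluded from matching.
#'
#' @param a,b annotation tibbles over the same document collection.
#' @param policy a [match_policy()].
#' @return a list with `pairs` (tibble of row indices `a_idx`, `b_idx`
#'   into the classed subsets `a_used`/`b_used`), `a_used`, `b_used`,
#'   `unmatched_a`, `unmatched_b` (annotation tibbles).
#' @export
match_spans <- function(a, b, policy = match_policy()) {
  a <- classed_only(a); b <- classed_only(b)
  ord_a <- order(a$doc_id, a$start, -(a$end - a$start), a$concept_class,
                 method = "radix")
  ord_b <- order(b$doc_id, b$start, -(b$end - b$start), b$concept_class,
                 method = "radix")
  a <- a[ord_a, , drop = FALSE]
  b <- b[ord_b, , drop = FALSE]
  na <- nrow(a); nb <- nrow(b)
  adj <- lapply(seq_len(na), function(i) {
    which(vapply(seq_len(nb), function(j) pair_compatible(a, i, b, j, policy),
                 logical(1)))
  })
  match_of_b <- rep(NA_integer_, nb)  # b index -> a index
  # greedy seed in (start, longest) order
  for (i in seq_len(na)) {
    free <- adj[[i]][is.na(match_of_b[adj[[i]]])]
    if (length(free) > 0) match_of_b[free[1]] <- i
  }
  # augmenting paths (Kuhn) for unmatched a mentions
  matched_a <- unique(match_of_b[!is.na(match_of_b)])
  try_augment <- function(i, visited) {
    for (j in adj[[i]]) {
      if (visited[j]) next
      visited[j] <- TRUE
      res <- if (is.na(match_of_b[j])) list(ok = TRUE, visited = visited)
             else {
               r <- try_augment(match_of_b[j], visited)
               list(ok = r$ok, visited = r$visited)
             }
      visited <- res$visited
      if (res$ok) {
        match_of_b[j] <<- i
        return(list(ok = TRUE, visited = visited))
      }
    }
    list(ok = FALSE, visited = visited)
  }
  for (i in setdiff(seq_len(na), matched_a)) {
    try_augment(i, rep(FALSE, nb))
  }
  pairs <- tibble::tibble(
    a_idx = match_of_b[!is.na(match_of_b)],
    b_idx = which(!is.na(match_of_b))
  )
  pairs <- pairs[order(pairs$a_idx), , drop = FALSE]
  list(pairs = pairs,
       a_used = a, b_used = b,
       unmatched_a = a[setdiff(seq_len(na), pairs$a_idx), , drop = FALSE],
       unmatched_b = b[setdiff(seq_len(nb), pairs$b_idx), , drop = FALSE])
}

score_row <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  r <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  f <- if (!is.na(p) && !is.na(r)) {
    if (p + r > 0) 2 * p * r / (p + r) else 0
  } else if (is.na(p) && is.na(r)) {
    NA_real_   # both sets empty: agreement undefined
  } else {
    0          # one side empty, the other not
  }
  tibble::tibble(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), precision = p, recall = r,
                 f_measure = f)
}

build_report <- function(m) {
  cls_of_pair <- m$a_used$concept_class[m$pairs$a_idx]
  rows <- lapply(CONCEPT_CLASSES, function(cls) {
    tp <- sum(cls_of_pair == cls)
    fp <- sum(m$unmatched_b$concept_class == cls)
    fn <- sum(m$unmatched_a$concept_class == cls)
    cbind(tibble::tibble(concept_class = cls), score_row(tp, fp, fn))
  })
  overall <- cbind(tibble::tibble(concept_class = "overall"),
                   score_row(nrow(m$pairs), nrow(m$unmatched_b),
                             nrow(m$unmatched_a)))
  rep <- do.call(rbind, c(rows, list(overall)))
  structure(rep, class = c("score_report", class(rep)))
}

#' Interannotator agreement between two annotation sets
#'
#' Matches the two sets under the policy and reports per-class and overall
#' counts and metrics, with `a` in the gold role and `b` in the predicted
#' role: TP = matched pairs, FP = unmatched in `b`, FN = unmatched in `a`.
#' Precision and recall swap under argument exchange, so the F-measure is
#' symmetric: `agreement(a, b)` and `agreement(b, a)` give equal F.  The
#' F-measure on the 0–100 scale is the agreement statistic ("IAA") used
#' for double-annotation reliability.
#'
#' @param a,b annotation tibbles.
#' @param policy a [match_policy()].
#' @return a `score_report` tibble: one row per concept class plus
#'   `"overall"`, columns `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f_measure` (percent; `NA` marks undefined ratios).
#' @export
agreement <- function(a, b, policy = match_policy()) {
  build_report(match_spans(a, b, policy))
}

#' Evaluate a system against a reference set
#'
#' Identical machinery to [agreement()], with the reference in the gold
#' role: reference mentions the system missed are false negatives, system
#' mentions absent from the reference are false positives.
#'
#' @param system system annotation tibble.
#' @param reference adjudicated reference annotation tibble.
#' @param policy a [match_policy()].
#' @return a `score_report` tibble.
#' @export
evaluate_system <- function(system, reference, policy = match_policy()) {
  agreement(reference, system, policy)
}

#' Build adjudication decisions
#'
#' @param doc_id,start,end,concept_class mention keys.
#' @param verdict `"KEEP"` or `"REJECT"` per key.
#' @param adjudicator adjudicator id.
#' @return a decisions tibble.
#' @export
adjudication_decisions <- function(doc_id = character(0), start = integer(0),
                                   end = integer(0),
                                   concept_class = character(0),
                                   verdict = character(0),
                                   adjudicator = "adjudicator") {
  v <- toupper(as.character(verdict))
  if (!all(v %in% c("KEEP", "REJECT"))) {
    abort_validation("verdicts must be KEEP or REJECT")
  }
  tibble::tibble(doc_id = as.character(doc_id), start = as.integer(start),
                 end = as.integer(end),
                 concept_class = as.character(concept_class),
                 verdict = v,
                 adjudicator = rep_len(as.character(adjudicator),
                                       length(doc_id)))
}

#' Read/write adjudication decisions (JSONL)
#'
#' One object per line with keys `doc_id`, `start`, `end`,
#' `concept_class`, `verdict`, `adjudicator`.
#'
#' @param path decisions file.
#' @return a decisions tibble.
#' @export
read_decisions <- function(path) {
  if (!file.exists(path)) {
    abort_validation(paste0("decisions file not found: ", path))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(adjudication_decisions())
  recs <- lapply(seq_along(lines), function(i) {
    rec <- jsonlite::fromJSON(lines[i])
    for (k in c("doc_id", "start", "end", "concept_class", "verdict")) {
      if (is.null(rec[[k]])) {
        abort_data(paste0("line ", i, ": decision missing '", k, "'"))
      }
    }
    adjudication_decisions(rec$doc_id, rec$start, rec$end, rec$concept_class,
                           rec$verdict,
                           if (is.null(rec$adjudicator)) "adjudicator"
                           else rec$adjudicator)
  })
  do.call(rbind, recs)
}

#' @rdname read_decisions
#' @param decisions a decisions tibble.
#' @export
write_decisions <- function(decisions, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(decisions))) {
    writeLines(jsonlite::toJSON(as.list(decisions[i, ]), auto_unbox = TRUE),
               con)
  }
  invisible(path)
}

mention_key <- function(x) paste(x$doc_id, x$start, x$end, x$concept_class)

#' Adjudicate two annotators into a reference set
#'
#' Third-coder adjudication: mentions on which the two annotators agree
#' (matched pairs; annotator `a`'s span is kept by convention) enter the
#' reference directly; every disagreement — a mention unmatched in either
#' set — must carry exactly one KEEP/REJECT verdict.  KEEP mentions join
#' the reference; REJECT mentions are dropped.
#'
#' @param a,b the two annotators' tibbles.
#' @param decisions a decisions tibble covering exactly the disagreements.
#' @param policy a [match_policy()].
#' @return an annotation tibble with source `"reference"`.
#' @export
adjudicate <- function(a, b, decisions = adjudication_decisions(),
                       policy = match_policy()) {
  m <- match_spans(a, b, policy)
  disputed <- rbind(m$unmatched_a, m$unmatched_b)
  dk <- mention_key(disputed)
  vk <- mention_key(decisions)
  missing <- setdiff(dk, vk)
  extra <- setdiff(vk, dk)
  if (length(missing) > 0 || length(extra) > 0) {
    abort_data(paste0(
      "adjudication coverage mismatch;",
      if (length(missing) > 0) paste0(" undecided: ",
                                      paste(missing, collapse = "; ")) else "",
      if (length(extra) > 0) paste0(" decisions for non-disagreements: ",
                                    paste(extra, collapse = "; ")) else ""))
  }
  keep <- disputed[decisions$verdict[match(dk, vk)] == "KEEP", , drop = FALSE]
  ref <- rbind(m$a_used[m$pairs$a_idx, , drop = FALSE], keep)
  if (nrow(ref) == 0) return(annotation_set(source = "reference"))
  annotation_set(ref$doc_id, ref$start, ref$end, ref$concept_class,
                 ref$category, ref$surface, source = "reference")
}

#' Error-analysis update of a reference set
#'
#' After a system run, each system false positive is re-adjudicated: if a
#' finding the system produced is deemed a valid instance, it is added to
#' the reference set and recounted as a true positive; otherwise it
#' remains a false positive.  The verdicts must cover exactly the system's
#' false positives under the policy.  The update can only add reference
#' mentions, so precision and recall never decrease.
#'
#' @param system system annotation tibble.
#' @param reference reference annotation tibble.
#' @param verdicts a decisions tibble over the system false positives.
#' @param policy a [match_policy()].
#' @return a list with `reference` (updated annotation tibble) and
#'   `report` (post-update `score_report`).
#' @export
error_analysis_update <- function(system, reference,
                                  verdicts = adjudication_decisions(),
                                  policy = match_policy()) {
  m <- match_spans(reference, system, policy)
  fps <- m$unmatched_b
  fk <- mention_key(fps)
  vk <- mention_key(verdicts)
  if (!setequal(fk, vk) || length(fk) != length(vk)) {
    abort_data(paste0("verdicts must cover exactly the system false ",
                      "positives; expected {",
                      paste(fk, collapse = "; "), "} got {",
                      paste(vk, collapse = "; "), "}"))
  }
  keep <- fps[verdicts$verdict[match(fk, vk)] == "KEEP", , drop = FALSE]
  ref2 <- rbind(reference, keep)
  ref2 <- annotation_set(ref2$doc_id, ref2$start, ref2$end,
                         ref2$concept_class, ref2$category, ref2$surface,
                         source = "reference")
  list(reference = ref2,
       report = evaluate_system(system, ref2, policy))
}

#' Format a score report
#'
#' Percentages are printed to one decimal place, rounding half up, the
#' convention used for reporting agreement in clinical annotation studies.
#'
#' @param x a `score_report`.
#' @param ... unused.
#' @return `format()` returns the character table; `print()` is called for
#'   its side effect.
#' @export
format.score_report <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "--",
                            sprintf("%.1f", round_half_up(v, 1)))
  header <- sprintf("%-8s %6s %6s %6s %10s %8s %8s",
                    "class", "TP", "FP", "FN", "precision", "recall", "F")
  body <- sprintf("%-8s %6d %6d %6d %10s %8s %8s",
                  x$concept_class, x$tp, x$fp, x$fn,
                  fmt(x$precision), fmt(x$recall), fmt(x$f_measure))
  c(header, body)
}

#' @rdname format.score_report
#' @export
print.score_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Serialize a score report as JSON
#'
#' @param x a `score_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_report <- function(x, path) {
  out <- lapply(seq_len(nrow(x)), function(i) {
    list(concept_class = x$concept_class[i], tp = x$tp[i], fp = x$fp[i],
         fn = x$fn[i],
         precision = if (is.na(x$precision[i])) NULL
                     else round_half_up(x$precision[i], 1),
         recall = if (is.na(x$recall[i])) NULL
                  else round_half_up(x$recall[i], 1),
         f_measure = if (is.na(x$f_measure[i])) NULL
                     else round_half_up(x$f_measure[i], 1))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}
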