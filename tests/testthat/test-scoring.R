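mk_ann <- function(spans, source = "a") {
  # spans: list of c(doc, start, end, class)
  if (length(spans) == 0) return(annotation_set(source = source))
  annotation_set(
    doc_id = vapply(spans, `[[`, character(1), 1),
    start = as.integer(vapply(spans, `[[`, character(1), 2)),
    end = as.integer(vapply(spans, `[[`, character(1), 3)),
    concept_class = vapply(spans, `[[`, character(1), 4),
    source = source)
}

row_of <- function(rep, cls) rep[rep$concept_class == cls, ]

test_that("match_spans: identity, overlap-vs-exact, and class gating", {
  a <- mk_ann(list(c("d", 0, 5, "AFFECT"), c("d", 10, 17, "AFFECT"),
                   c("d", 20, 24, "MOOD"), c("d", 30, 33, "MOOD")))
  m <- match_spans(a, mk_ann(a_to_list(a), source = "b"))
  expect_equal(nrow(m$pairs), 4)
  expect_equal(nrow(m$unmatched_a) + nrow(m$unmatched_b), 0)

  a1 <- mk_ann(list(c("d", 10, 17, "AFFECT")))
  b1 <- mk_ann(list(c("d", 12, 20, "AFFECT")), source = "b")
  expect_equal(nrow(match_spans(a1, b1, match_policy("OVERLAP"))$pairs), 1)
  expect_equal(nrow(match_spans(a1, b1, match_policy("EXACT"))$pairs), 0)

  b2 <- mk_ann(list(c("d", 10, 17, "MOOD")), source = "b")
  expect_equal(nrow(match_spans(a1, b2)$pairs), 0)
  expect_equal(nrow(match_spans(a1, b2, match_policy("OVERLAP", FALSE))$pairs), 1)
})

test_that("agreement reproduces the direct formula", {
  # a has 4 mentions, b has 5, 3 matched -> P=60, R=75, F=66.7
  a <- mk_ann(list(c("d", 0, 5, "AFFECT"), c("d", 10, 15, "AFFECT"),
                   c("d", 20, 25, "MOOD"), c("d", 30, 35, "MOOD")))
  b <- mk_ann(list(c("d", 0, 5, "AFFECT"), c("d", 10, 15, "AFFECT"),
                   c("d", 20, 25, "MOOD"), c("d", 40, 45, "MOOD"),
                   c("d", 50, 55, "AFFECT")), source = "b")
  rep <- agreement(a, b)
  ov <- row_of(rep, "overall")
  expect_equal(ov$tp, 3); expect_equal(ov$fp, 2); expect_equal(ov$fn, 1)
  expect_equal(round_half_up(ov$precision, 1), 60.0)
  expect_equal(round_half_up(ov$recall, 1), 75.0)
  expect_equal(round_half_up(ov$f_measure, 1), 66.7)
})

test_that("agreement: identity gives 100, disjoint gives 0, empties flagged", {
  a <- mk_ann(list(c("d", 0, 5, "AFFECT"), c("d", 9, 14, "MOOD")))
  b <- mk_ann(a_to_list(a), source = "b")
  expect_equal(row_of(agreement(a, b), "overall")$f_measure, 100)

  disj <- mk_ann(list(c("d", 20, 25, "AFFECT")), source = "b")
  expect_equal(row_of(agreement(a, disj), "overall")$f_measure, 0)

  emptyb <- annotation_set(source = "b")
  rep <- agreement(a, emptyb)
  ov <- row_of(rep, "overall")
  expect_true(is.na(ov$precision))  # no predictions: precision undefined
  expect_equal(ov$recall, 0)
  expect_equal(ov$f_measure, 0)
})

test_that("F is symmetric and bounded by min/max of P and R (property)", {
  set.seed(71)
  docs <- corpus(paste0("d", 1:3), rep(strrep("x", 60), 3))
  for (i in 1:40) {
    a <- rand_annotations(docs, "a")
    b <- rand_annotations(docs, "b")
    for (mode in c("OVERLAP", "EXACT")) {
      pol <- match_policy(mode)
      r1 <- row_of(agreement(a, b, pol), "overall")
      r2 <- row_of(agreement(b, a, pol), "overall")
      expect_equal(r1$f_measure, r2$f_measure, tolerance = 1e-12)
      if (!is.na(r1$precision) && !is.na(r1$recall)) {
        expect_gte(r1$f_measure + 1e-9, min(r1$precision, r1$recall))
        expect_lte(r1$f_measure - 1e-9, max(r1$precision, r1$recall))
      }
      # count conservation
      expect_equal(r1$tp + r1$fn, sum(!is.na(a$concept_class)))
      expect_equal(r1$tp + r1$fp, sum(!is.na(b$concept_class)))
    }
  }
})

test_that("pairing size equals exhaustive maximum matching (property)", {
  set.seed(83)
  docs <- corpus("d1", strrep("y", 40))
  for (i in 1:40) {
    a <- rand_annotations(docs, "a", max_per_doc = 8)
    b <- rand_annotations(docs, "b", max_per_doc = 8)
    for (mode in c("OVERLAP", "EXACT")) {
      pol <- match_policy(mode)
      got <- nrow(match_spans(a, b, pol)$pairs)
      expect_equal(got, oracle_max_matching(a, b, pol),
                   info = paste("fixture", i, mode))
    }
  }
})

test_that("adding an agreeing mention to both sets never decreases F", {
  set.seed(19)
  docs <- corpus("d1", strrep("z", 120))
  for (i in 1:20) {
    a <- rand_annotations(docs, "a")
    b <- rand_annotations(docs, "b")
    f0 <- row_of(agreement(a, b), "overall")$f_measure
    extra <- annotation_set("d1", 100L, 110L, "AFFECT", source = "x")
    a2 <- annotation_set(c(a$doc_id, "d1"), c(a$start, 100L), c(a$end, 110L),
                         c(a$concept_class, "AFFECT"), source = "a")
    b2 <- annotation_set(c(b$doc_id, "d1"), c(b$start, 100L), c(b$end, 110L),
                         c(b$concept_class, "AFFECT"), source = "b")
    f1 <- row_of(agreement(a2, b2), "overall")$f_measure
    if (!is.na(f0)) expect_gte(f1 + 1e-9, f0)
  }
})

test_that("adjudication builds the reference from agreements plus KEEP verdicts", {
  a <- mk_ann(list(c("d", 0, 5, "AFFECT"), c("d", 10, 15, "MOOD")))
  b <- mk_ann(list(c("d", 0, 5, "AFFECT"), c("d", 20, 25, "MOOD")), source = "b")
  # disagreements: a's (10,15,MOOD) and b's (20,25,MOOD)
  dec <- adjudication_decisions(c("d", "d"), c(10L, 20L), c(15L, 25L),
                                c("MOOD", "MOOD"), c("KEEP", "REJECT"))
  ref <- adjudicate(a, b, dec)
  expect_identical(unique(ref$source), "reference")
  key <- paste(ref$start, ref$end, ref$concept_class)
  expect_setequal(key, c("0 5 AFFECT", "10 15 MOOD"))

  # fully agreeing sets need no decisions and reproduce a
  refid <- adjudicate(a, mk_ann(a_to_list(a), source = "b"))
  expect_equal(nrow(refid), nrow(a))
})

test_that("adjudication coverage mismatches are rejected with keys listed", {
  a <- mk_ann(list(c("d", 0, 5, "AFFECT")))
  b <- mk_ann(list(c("d", 20, 25, "MOOD")), source = "b")
  expect_error(adjudicate(a, b), "undecided")
  toomany <- adjudication_decisions(c("d", "d", "d"), c(0L, 20L, 40L),
                                    c(5L, 25L, 45L),
                                    c("AFFECT", "MOOD", "MOOD"),
                                    c("KEEP", "KEEP", "REJECT"))
  expect_error(adjudicate(a, b, toomany), "non-disagreement")
})

test_that("evaluate_system treats the reference as gold", {
  ref <- mk_ann(lapply(0:9, function(i) c("d", i * 10, i * 10 + 5, "AFFECT")),
                source = "reference")
  sys <- mk_ann(lapply(0:8, function(i) c("d", i * 10, i * 10 + 5, "AFFECT")),
                source = "system")
  ov <- row_of(evaluate_system(sys, ref), "overall")
  expect_equal(ov$precision, 100)
  expect_equal(ov$recall, 90)

  same <- evaluate_system(ref, ref)
  expect_true(all(stats::na.omit(same$f_measure) == 100))

  degenerate <- row_of(evaluate_system(annotation_set(source = "system"), ref),
                       "overall")
  expect_equal(degenerate$recall, 0)
  expect_true(is.na(degenerate$precision))
  expect_equal(degenerate$f_measure, 0)
})

test_that("error-analysis update promotes KEEP false positives to TP", {
  ref <- mk_ann(lapply(0:9, function(i) c("d", i * 10, i * 10 + 5, "AFFECT")),
                source = "reference")
  # system: 8 of the reference mentions + 2 spurious
  sys <- mk_ann(c(lapply(0:7, function(i) c("d", i * 10, i * 10 + 5, "AFFECT")),
                  list(c("d", 200, 205, "AFFECT"), c("d", 210, 215, "AFFECT"))),
                source = "system")
  before <- row_of(evaluate_system(sys, ref), "overall")
  expect_equal(before$tp, 8); expect_equal(before$fp, 2)

  ver <- adjudication_decisions(c("d", "d"), c(200L, 210L), c(205L, 215L),
                                c("AFFECT", "AFFECT"), c("KEEP", "REJECT"))
  upd <- error_analysis_update(sys, ref, ver)
  after <- row_of(upd$report, "overall")
  expect_equal(after$tp, 9); expect_equal(after$fp, 1)
  expect_equal(after$tp + after$fp, nrow(sys))        # system count unchanged
  expect_equal(nrow(upd$reference), nrow(ref) + 1)    # superset by one KEEP
  expect_gte(after$precision, before$precision)
  expect_gte(after$recall, before$recall)

  # all REJECT leaves the report unchanged
  ver2 <- adjudication_decisions(c("d", "d"), c(200L, 210L), c(205L, 215L),
                                 c("AFFECT", "AFFECT"), c("REJECT", "REJECT"))
  upd2 <- error_analysis_update(sys, ref, ver2)
  expect_equal(row_of(upd2$report, "overall")$tp, before$tp)

  # no FPs: verdicts must be empty and report is unchanged
  sys3 <- mk_ann(lapply(0:7, function(i) c("d", i * 10, i * 10 + 5, "AFFECT")),
                 source = "system")
  upd3 <- error_analysis_update(sys3, ref)
  expect_equal(row_of(upd3$report, "overall")$fp, 0)
  expect_error(error_analysis_update(sys3, ref, ver), "cover exactly")
})

test_that("error-analysis update never decreases precision or recall (property)", {
  set.seed(59)
  docs <- corpus("d1", strrep("w", 80))
  for (i in 1:25) {
    ref <- rand_annotations(docs, "reference")
    sys <- rand_annotations(docs, "system")
    m <- match_spans(ref, sys)
    fps <- m$unmatched_b
    if (nrow(fps) == 0) next
    ver <- adjudication_decisions(fps$doc_id, fps$start, fps$end,
                                  fps$concept_class,
                                  sample(c("KEEP", "REJECT"), nrow(fps),
                                         replace = TRUE))
    before <- row_of(evaluate_system(sys, ref), "overall")
    after <- row_of(error_analysis_update(sys, ref, ver)$report, "overall")
    if (!is.na(before$precision)) expect_gte(after$precision + 1e-9, before$precision)
    if (!is.na(before$recall)) expect_gte(after$recall + 1e-9, before$recall)
    expect_equal(after$tp + after$fp, sum(!is.na(sys$concept_class)))
  }
})

test_that("score reports print to one decimal, rounding half up", {
  expect_equal(round_half_up(66.65, 1), 66.7)
  expect_equal(round_half_up(83.6734, 1), 83.7)
  a <- mk_ann(list(c("d", 0, 5, "AFFECT"), c("d", 10, 15, "AFFECT"),
                   c("d", 20, 25, "AFFECT")))
  b <- mk_ann(list(c("d", 0, 5, "AFFECT"), c("d", 30, 35, "AFFECT")),
              source = "b")
  txt <- format(agreement(a, b))
  expect_true(any(grepl("overall", txt)))
  expect_true(any(grepl("40.0", txt)))  # F = 2*.5*(1/3)/(5/6) = 40%
})
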