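test_that("read_corpus reads JSONL records in sorted order with metadata", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"doc_id":"c","text":"third note"}',
    '{"doc_id":"a","text":"first note","note_type":"Psychiatry medication management"}',
    '{"doc_id":"b","text":"second note","provider_type":"psychology"}'), path)
  docs <- read_corpus(path)
  expect_equal(docs$doc_id, c("a", "b", "c"))
  expect_identical(docs$note_type[1], "Psychiatry medication management")
  expect_identical(docs$provider_type[2], "psychology")
})

test_that("read_corpus reads a directory of txt files using file stems as ids", {
  dir <- withr::local_tempdir()
  writeLines("alpha text", file.path(dir, "a.txt"))
  writeLines("beta text", file.path(dir, "b.txt"))
  docs <- read_corpus(dir)
  expect_equal(docs$doc_id, c("a", "b"))
  expect_equal(docs$text, c("alpha text", "beta text"))
})

test_that("read_corpus rejects duplicates and records without text", {
  p1 <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"doc_id":"a","text":"x"}', '{"doc_id":"a","text":"y"}'), p1)
  expect_error(read_corpus(p1), "duplicate doc_id.*a")
  p2 <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"doc_id":"a","text":"x"}', '{"doc_id":"b"}'), p2)
  expect_error(read_corpus(p2), "line 2")
})

test_that("annotations round-trip through both standoff dialects", {
  docs <- corpus(c("d1", "d2"),
                 c("Mood: depressed. Affect: flat today.",
                   "He was anxious and tearful throughout."))
  ann <- annotation_set(
    doc_id = c("d1", "d1", "d2", "d2", "d2"),
    start = c(6L, 25L, 7L, 19L, 7L),
    end = c(15L, 29L, 14L, 26L, 14L),
    concept_class = c("MOOD", "AFFECT", "AFFECT", "AFFECT", "MOOD"),
    category = c("DESCRIPTIVE", "DESCRIPTIVE", NA, "DESCRIPTIVE", NA),
    source = "annA")
  ann <- validate_annotations(ann, docs)

  jl <- withr::local_tempfile(fileext = ".jsonl")
  write_annotations(ann, jl, dialect = "jsonl")
  back <- read_annotations(jl, docs)
  expect_equal(as.data.frame(back), as.data.frame(ann))

  for (id in c("d1", "d2")) {
    xf <- withr::local_tempfile(fileext = ".xml")
    sub <- ann[ann$doc_id == id, ]
    write_annotations(sub, xf, dialect = "xml")
    backx <- read_annotations(xf, docs)
    expect_equal(as.data.frame(backx), as.data.frame(sub))
  }
})

test_that("an empty annotation set round-trips in both dialects", {
  docs <- corpus("d1", "some text")
  empty <- annotation_set(source = "annA")
  for (d in c("jsonl", "xml")) {
    f <- withr::local_tempfile()
    write_annotations(empty, f, dialect = d)
    expect_equal(nrow(read_annotations(f, docs)), 0)
  }
})

test_that("offsets are code-point offsets: non-ASCII text round-trips", {
  docs <- corpus("d1", "café visit — patient’s affect flat today")
  start <- regexpr("flat", docs$text, fixed = TRUE)[1] - 1L
  ann <- annotation_set("d1", start, start + 4L, "AFFECT", source = "annA")
  ann <- validate_annotations(ann, docs)
  expect_identical(ann$surface, "flat")
  for (d in c("jsonl", "xml")) {
    f <- withr::local_tempfile()
    write_annotations(ann, f, dialect = d)
    back <- read_annotations(f, docs)
    expect_equal(back$start, ann$start)
    expect_identical(back$surface, "flat")
  }
})

test_that("surfaces are re-derived from text; disagreements warn and lose", {
  docs <- corpus("d1", "0123456789abcdefghij")
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(paste0('{"doc_id":"d1","start":10,"end":17,',
                    '"concept_class":"AFFECT","surface":"WRONG","source":"annA"}'), f)
  expect_warning(ann <- read_annotations(f, docs), "disagrees")
  expect_identical(ann$surface, "abcdefg")
})

test_that("spans outside the document and bad classes are rejected", {
  docs <- corpus("d1", "short")
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines('{"doc_id":"d1","start":2,"end":99,"concept_class":"AFFECT","source":"a"}', f)
  expect_error(read_annotations(f, docs), "outside document")
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  writeLines('{"doc_id":"d1","start":0,"end":3,"concept_class":"JOY","source":"a"}', f2)
  expect_error(read_annotations(f2, docs), "not AFFECT or MOOD")
})

test_that("two annotators' files for one document keep distinct source labels", {
  docs <- corpus("d1", "affect flat today during the visit")
  a <- annotation_set("d1", 7L, 11L, "AFFECT", source = "annA")
  b <- annotation_set("d1", 7L, 11L, "AFFECT", source = "annB")
  fa <- withr::local_tempfile(fileext = ".jsonl")
  fb <- withr::local_tempfile(fileext = ".jsonl")
  write_annotations(validate_annotations(a, docs), fa)
  write_annotations(validate_annotations(b, docs), fb)
  expect_identical(unique(read_annotations(fa, docs)$source), "annA")
  expect_identical(unique(read_annotations(fb, docs)$source), "annB")
})

test_that("round-trip equality holds on random annotation sets (property)", {
  set.seed(97)
  docs <- corpus(paste0("doc", 1:4),
                 vapply(1:4, function(i) {
                   paste(rand_word(sample(8:20, 1)), collapse = " ")
                 }, character(1)))
  for (rep in 1:40) {
    ann <- rand_annotations(docs, source = "annX")
    ann <- validate_annotations(ann, docs)
    jl <- tempfile(fileext = ".jsonl")
    write_annotations(ann, jl, dialect = "jsonl")
    expect_equal(as.data.frame(read_annotations(jl, docs)),
                 as.data.frame(ann))
    unlink(jl)
    for (id in unique(ann$doc_id)) {
      xf <- tempfile(fileext = ".xml")
      sub <- ann[ann$doc_id == id, ]
      write_annotations(sub, xf, dialect = "xml")
      expect_equal(as.data.frame(read_annotations(xf, docs)),
                   as.data.frame(sub))
      unlink(xf)
    }
  }
})
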