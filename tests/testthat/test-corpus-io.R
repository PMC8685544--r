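test_that("JSONL documents round-trip in order and malformed records name their line", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  docs <- data.frame(doc_id = c("a", "b"), agency = c("FDA", "EMA"),
                     section = "Warnings and Precautions",
                     text = c("Hepatitis has been reported.", "Monitor ALT."),
                     dili_label = c(1L, NA_integer_), stringsAsFactors = FALSE)
  write_documents(docs, path)
  back <- read_documents(path)
  expect_equal(back, docs)

  writeLines(c('{"doc_id":"a","text":"ok"}', '{"doc_id":"b"}'), path)
  expect_error(read_documents(path), "line 2")
  writeLines(c('{"doc_id":"a","text":"ok"}', 'not json'), path)
  expect_error(read_documents(path), "line 2")
  writeLines(rep('{"doc_id":"a","text":"ok"}', 2), path)
  expect_error(read_documents(path), "duplicate doc_id")
})

test_that("a 750-record corpus reads back as 750 documents", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(sprintf('{"doc_id":"d%03d","text":"Sentence %d."', seq_len(750), seq_len(750)) |>
               paste0("}"), path)
  expect_identical(nrow(read_documents(path)), 750L)
})

test_that("sentence splitting honors terminators, decimals and abbreviations", {
  expect_equal(split_sentences("Hepatitis has been reported. Monitor ALT."),
               c("Hepatitis has been reported.", "Monitor ALT."))
  expect_length(split_sentences("Doses of 2.5 mg were studied."), 1L)
  expect_length(split_sentences("Monitor liver enzymes, e.g. ALT and AST, monthly."), 1L)
  expect_length(split_sentences("Administer i.v. Infusion takes 30 minutes."), 1L)
  expect_identical(split_sentences(""), character(0))
  # total and deterministic on arbitrary non-empty text
  set.seed(7)
  for (i in 1:25) {
    junk <- paste(sample(c(letters, ".", "?", "!", " ", "5", "A"), 40, replace = TRUE),
                  collapse = "")
    expect_identical(split_sentences(junk), split_sentences(junk))
  }
})

test_that("generator sentence boundaries round-trip through the splitter", {
  corpus <- fx_corpus()
  led <- corpus$ledger
  for (id in head(corpus$documents$doc_id, 10)) {
    doc <- corpus$documents[corpus$documents$doc_id == id, ]
    got <- split_sentences(doc$text)
    want <- led$text[led$doc_id == id]
    expect_identical(got, want)
  }
})

test_that("sentence deduplication is exact, first-kept and idempotent", {
  s <- data.frame(doc_id = c("a", "a", "b", "b"), index = c(1, 2, 1, 2),
                  text = c("Monitor  ALT.", "Monitor ALT.", "monitor alt.", "Other."),
                  stringsAsFactors = FALSE)
  u <- unique_sentences(s)
  expect_identical(u$text, c("Monitor  ALT.", "monitor alt.", "Other."))
  expect_identical(unique_sentences(u), u)
  # generated corpus: unique count matches the generator's own inventory
  led <- fx_corpus()$ledger
  expect_identical(nrow(unique_sentences(led)), attr(led, "n_unique"))
})

test_that("stratified splits reproduce the published document counts", {
  mk <- function(sizes) {
    data.frame(doc_id = sprintf("d%04d", seq_len(sum(sizes))),
               stratum = rep(seq_along(sizes), sizes), stringsAsFactors = FALSE)
  }
  sp <- stratified_split(mk(c(250, 500)), "stratum", 0.2, seed = 3)
  expect_identical(c(nrow(sp$train), nrow(sp$test)), c(600L, 150L))
  # 540 documents over three strata where per-stratum banker's rounding
  # yields the published 431/109 partition
  sp <- stratified_split(mk(c(153, 153, 234)), "stratum", 0.2, seed = 3)
  expect_identical(c(nrow(sp$train), nrow(sp$test)), c(431L, 109L))
  for (seed in 1:5) {
    sp <- stratified_split(mk(10), "stratum", 0.2, seed = seed)
    expect_identical(c(nrow(sp$train), nrow(sp$test)), c(8L, 2L))
  }
  expect_error(stratified_split(mk(10), "stratum", 1.2), "test_fraction")
})

test_that("stratified splits partition exactly and preserve stratum proportions", {
  set.seed(11)
  for (i in 1:10) {
    sizes <- sample(5:60, sample(2:4, 1))
    df <- data.frame(id = seq_len(sum(sizes)),
                     stratum = rep(seq_along(sizes), sizes))
    frac <- runif(1, 0.1, 0.4)
    sp <- stratified_split(df, "stratum", frac, seed = i)
    expect_setequal(c(sp$train$id, sp$test$id), df$id)
    expect_length(intersect(sp$train$id, sp$test$id), 0L)
    for (s in seq_along(sizes)) {
      n_test <- sum(sp$test$stratum == s)
      expect_lte(abs(n_test - sizes[s] * frac), 0.5 + 1e-9)
    }
    sp2 <- stratified_split(df, "stratum", frac, seed = i)
    expect_identical(sp$test$id, sp2$test$id)
  }
})

test_that("CoNLL files round-trip, repair dangling tags and reject foreign tags", {
  path <- withr::local_tempfile(fileext = ".conll")
  set.seed(5)
  seqs <- lapply(sample(3:12, 100, replace = TRUE), random_iob_seq)
  write_conll(seqs, path)
  expect_identical(read_conll(path), seqs)

  writeLines(c("monitor\tO", "hepatitis\tI-LIVER", ""), path)
  expect_warning(back <- read_conll(path), "repaired")
  expect_identical(back[[1]]$tags, c("O", "B-LIVER"))
  # repair is idempotent
  expect_identical(repair_iob(back[[1]]$tags, warn = FALSE), back[[1]]$tags)

  writeLines(c("aspirin\tB-DRUG", ""), path)
  expect_error(read_conll(path), "line 1")
  writeLines("token O extra", path)
  expect_error(read_conll(path), "two columns")
})
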