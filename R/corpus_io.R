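#' Read drug labeling documents
#'
#' Reads one labeling section per document, either from a JSON-lines file
#' (one record per line with keys `doc_id`, `agency`, `section`, `text`,
#' `dili_label`) or from a directory of plain-text files (one document per
#' `*.txt` file; the file stem becomes the `doc_id`).
#'
#' @param path path to a `.jsonl` file or a directory of `.txt` files.
#' @param format input layout, `"jsonl"` (default) or `"plaintext-dir"`.
#' @return a data frame with columns `doc_id`, `agency`, `section`, `text`
#'   and `dili_label` (0/1 or `NA` when the document is unlabeled), in file
#'   order.
#' @details Records missing `doc_id` or `text` raise an error naming the
#'   offending line; duplicated `doc_id`s raise an error. A labeled document
#'   (non-missing `dili_label`) must have non-empty text.
#' @export
read_documents <- function(path, format = c("jsonl", "plaintext-dir")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("path does not exist: %s", path)
  if (format == "plaintext-dir") {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    docs <- data.frame(
      doc_id = sub("\\.txt$", "", basename(files)),
      agency = NA_character_,
      section = NA_character_,
      text = vapply(files, function(f) paste(readLines(f, warn = FALSE), collapse = " "),
                    character(1)),
      dili_label = NA_integer_,
      stringsAsFactors = FALSE
    )
    rownames(docs) <- NULL
    return(validate_documents(docs))
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(trimws(lines))
  recs <- vector("list", sum(keep))
  j <- 0L
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stopf("malformed JSON record at line %d: %s", i, conditionMessage(e)))
    if (is.null(rec$doc_id) || !nzchar(rec$doc_id)) stopf("record at line %d is missing doc_id", i)
    if (is.null(rec$text)) stopf("record at line %d is missing text", i)
    j <- j + 1L
    recs[[j]] <- data.frame(
      doc_id = as.character(rec$doc_id),
      agency = if (is.null(rec$agency)) NA_character_ else as.character(rec$agency),
      section = if (is.null(rec$section)) NA_character_ else as.character(rec$section),
      text = as.character(rec$text),
      dili_label = if (is.null(rec$dili_label) || is.na(rec$dili_label)[1]) NA_integer_ else as.integer(rec$dili_label),
      stringsAsFactors = FALSE
    )
  }
  docs <- do.call(rbind, recs)
  validate_documents(docs)
}

validate_documents <- function(docs) {
  dup <- docs$doc_id[duplicated(docs$doc_id)]
  if (length(dup)) stopf("duplicate doc_id: %s", paste(unique(dup), collapse = ", "))
  bad <- !is.na(docs$dili_label) & !nzchar(trimws(docs$text))
  if (any(bad)) stopf("labeled document with empty text: %s",
                      paste(docs$doc_id[bad], collapse = ", "))
  ok_lab <- is.na(docs$dili_label) | docs$dili_label %in% c(0L, 1L)
  if (!all(ok_lab)) stopf("dili_label must be 0, 1 or missing")
  docs
}

#' Write documents as JSON lines
#'
#' @param docs document data frame as returned by [read_documents()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_documents <- function(docs, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(docs))) {
    rec <- list(doc_id = docs$doc_id[i], agency = docs$agency[i],
                section = docs$section[i], text = docs$text[i],
                dili_label = docs$dili_label[i])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null"), con,
               useBytes = TRUE)
  }
  invisible(path)
}

# clinical abbreviations that must not terminate a sentence
SENT_ABBREV <- c("e.g", "i.e", "i.v", "i.m", "s.c", "p.o", "b.i.d", "t.i.d",
                 "q.d", "vs", "etc", "approx", "dr", "mr", "mrs", "ms", "st",
                 "fig", "no", "al", "inc", "ltd", "co", "spp", "resp", "wk",
                 "mo", "min", "max")

#' Split a labeling section into sentences
#'
#' Deterministic rule-based splitter: a sentence boundary is a run of
#' `.`, `!` or `?` followed by whitespace and an upper-case letter, digit or
#' opening parenthesis. Decimal numbers never split (no whitespace follows
#' the period), and a guard list of clinical abbreviations ("e.g.", "i.v.",
#' "Fig.", ...) suppresses boundaries after abbreviations.
#'
#' @param text a character scalar (one document's section text).
#' @return character vector of sentences, in order; `character(0)` for empty
#'   input.
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- squish(text)
  if (!nzchar(text)) return(character(0))
  m <- gregexpr("[.!?]+(?=\\s+[A-Z0-9(])", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(text)
  ends <- as.integer(m) + attr(m, "match.length") - 1L
  # drop boundaries whose preceding word is a guarded abbreviation
  keep <- vapply(seq_along(ends), function(i) {
    before <- substr(text, 1L, as.integer(m)[i] - 1L)
    last_word <- regmatches(before, regexpr("[[:alnum:].]+$", before))
    if (!length(last_word)) return(TRUE)
    !(tolower(last_word) %in% SENT_ABBREV)
  }, logical(1))
  ends <- ends[keep]
  if (!length(ends)) return(text)
  starts <- c(1L, ends + 1L)
  stops <- c(ends, nchar(text))
  out <- substring(text, starts, stops)
  out <- squish(out)
  out[nzchar(out)]
}

#' Tokenize a sentence into word tokens
#'
#' Splits on whitespace and punctuation while keeping alphanumeric units
#' with internal hyphens, slashes, apostrophes or decimal points intact
#' (e.g. "SGOT/AST", "beta-hemolytic", "2.5" each stay one token).
#' Punctuation characters become single-character tokens.
#'
#' @param text character vector of sentences.
#' @return a list of character vectors, one per input sentence.
#' @export
tokenize_words <- function(text) {
  pat <- "[A-Za-z0-9]+(?:[-/.'][A-Za-z0-9]+)*|[^\\sA-Za-z0-9]"
  out <- regmatches(text, gregexpr(pat, text, perl = TRUE))
  lapply(out, as.character)
}

#' Sentence table for a document corpus
#'
#' Applies [split_sentences()] to every document and returns one row per
#' sentence with its within-document index.
#'
#' @param docs document data frame.
#' @return data frame with columns `doc_id`, `index` (1-based, contiguous)
#'   and `text`.
#' @export
corpus_sentences <- function(docs) {
  parts <- lapply(seq_len(nrow(docs)), function(i) {
    s <- split_sentences(docs$text[i])
    if (!length(s)) return(NULL)
    data.frame(doc_id = docs$doc_id[i], index = seq_along(s), text = s,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) {
    out <- data.frame(doc_id = character(0), index = integer(0),
                      text = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Deduplicate sentences by exact text
#'
#' Case-sensitive exact-match deduplication after whitespace normalization;
#' the first occurrence (in input order) is kept, so the operation is
#' idempotent and order-deterministic.
#'
#' @param sentences sentence data frame with a `text` column (e.g. from
#'   [corpus_sentences()]).
#' @return the subset of `sentences` with unique normalized text.
#' @export
unique_sentences <- function(sentences) {
  key <- squish(sentences$text)
  out <- sentences[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stratified train/test split
#'
#' Splits rows into disjoint, exhaustive train and test partitions. The test
#' count within each stratum is `round(stratum_size * test_fraction)` under
#' round-half-to-even, with the remainder going to train, so class
#' proportions are preserved within one item per stratum. The same seed
#' always yields the same split.
#'
#' @param data data frame to split.
#' @param stratify_on name of the column defining strata.
#' @param test_fraction fraction held out for test, in (0, 1).
#' @param seed integer seed controlling the within-stratum draw.
#' @return a list with elements `train` and `test` (data frames).
#' @export
stratified_split <- function(data, stratify_on, test_fraction, seed = 1L) {
  if (!is_prob(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    stopf("test_fraction must be in (0, 1)")
  }
  if (!stratify_on %in% names(data)) stopf("missing stratification field: %s", stratify_on)
  strata <- as.character(data[[stratify_on]])
  if (anyNA(strata)) stopf("stratification field has missing values")
  idx_test <- with_seed(as.integer(seed), {
    unlist(lapply(split(seq_len(nrow(data)), strata), function(idx) {
      n_test <- round(length(idx) * test_fraction)
      if (n_test == 0L) return(integer(0))
      sort(sample(idx, n_test))
    }), use.names = FALSE)
  })
  idx_test <- sort(idx_test)
  list(train = data[setdiff(seq_len(nrow(data)), idx_test), , drop = FALSE],
       test = data[idx_test, , drop = FALSE])
}

#' Persist a document split assignment
#'
#' @param split a list with `train` and `test` data frames carrying `doc_id`.
#' @param path output TSV path (columns `doc_id`, `partition`).
#' @return `path`, invisibly.
#' @export
write_split <- function(split, path) {
  tab <- rbind(
    data.frame(doc_id = split$train$doc_id, partition = "train", stringsAsFactors = FALSE),
    data.frame(doc_id = split$test$doc_id, partition = "test", stringsAsFactors = FALSE)
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Repair an IOB tag sequence
#'
#' A dangling `I-LIVER` (not preceded by `B-LIVER` or `I-LIVER`) is repaired
#' to `B-LIVER`. The repair is idempotent.
#'
#' @param tags character vector over `O`, `B-LIVER`, `I-LIVER`.
#' @param warn emit a warning when a repair is applied.
#' @return repaired tag vector.
#' @export
repair_iob <- function(tags, warn = TRUE) {
  repaired <- FALSE
  for (i in seq_along(tags)) {
    if (tags[i] == "I-LIVER") {
      prev <- if (i == 1L) "O" else tags[i - 1L]
      if (!prev %in% LIVER_TAGS) {
        tags[i] <- "B-LIVER"
        repaired <- TRUE
      }
    }
  }
  if (repaired && warn) warnf("dangling I-LIVER repaired to B-LIVER")
  tags
}

#' Read token-annotated sentences (CoNLL-style)
#'
#' Two whitespace-separated columns (token, IOB tag); a blank line separates
#' sentences. Tags outside `{O, B-LIVER, I-LIVER}` raise an error naming the
#' line; dangling `I-LIVER` tags are repaired to `B-LIVER` with a warning.
#'
#' @param path input file.
#' @return a list of sequences, each a list with `tokens` and `tags`
#'   character vectors of equal length.
#' @export
read_conll <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  seqs <- list()
  tok <- character(0)
  tag <- character(0)
  flush <- function() {
    if (length(tok)) {
      seqs[[length(seqs) + 1L]] <<- list(tokens = tok, tags = repair_iob(tag))
    }
    tok <<- character(0)
    tag <<- character(0)
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) {
      flush()
      next
    }
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2L) stopf("line %d: expected two columns, got %d", i, length(parts))
    if (!parts[2] %in% IOB_TAGSET) stopf("line %d: tag outside tagset: %s", i, parts[2])
    tok <- c(tok, parts[1])
    tag <- c(tag, parts[2])
  }
  flush()
  seqs
}

#' Write token-annotated sentences (CoNLL-style)
#'
#' @param seqs list of sequences (`tokens`, `tags`), e.g. from [read_conll()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_conll <- function(seqs, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (s in seqs) {
    stopifnot(length(s$tokens) == length(s$tags))
    writeLines(paste(s$tokens, s$tags, sep = "\t"), con, useBytes = TRUE)
    writeLines("", con, useBytes = TRUE)
  }
  invisible(path)
}
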