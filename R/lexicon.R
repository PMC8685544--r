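#' Construct a pattern lexicon
#'
#' A lexicon is a named set of string patterns with a matching mode.
#' `substring-stem` patterns match anywhere inside a sentence (so the stem
#' "hepat" covers hepatic, hepatitis, hepatotoxicity); `word-boundary`
#' patterns only match as whole words, which is the right mode for short
#' enzyme abbreviations (ALT, AST) that would otherwise fire inside
#' unrelated words. Mode can be set per pattern.
#'
#' @param patterns character vector of patterns.
#' @param mode default matching mode, `"substring-stem"` or
#'   `"word-boundary"`.
#' @param case_insensitive fold case before matching (default `TRUE`).
#' @param name lexicon name.
#' @param pattern_mode optional per-pattern mode vector overriding `mode`.
#' @return an object of class `dili_lexicon`.
#' @export
lexicon <- function(patterns, mode = c("substring-stem", "word-boundary"),
                    case_insensitive = TRUE, name = "lexicon",
                    pattern_mode = NULL) {
  mode <- match.arg(mode)
  patterns <- squish(patterns)
  if (!length(patterns) || any(!nzchar(patterns))) stopf("lexicon patterns must be non-empty")
  if (is.null(pattern_mode)) pattern_mode <- rep(mode, length(patterns))
  stopifnot(length(pattern_mode) == length(patterns),
            all(pattern_mode %in% c("substring-stem", "word-boundary")))
  key <- if (case_insensitive) tolower(patterns) else patterns
  if (anyDuplicated(key)) stopf("duplicate lexicon patterns after case folding")
  structure(list(name = name, patterns = patterns, mode = mode,
                 pattern_mode = pattern_mode,
                 case_insensitive = isTRUE(case_insensitive)),
            class = "dili_lexicon")
}

#' @export
print.dili_lexicon <- function(x, ...) {
  cat(sprintf("<dili_lexicon> %s: %d patterns, mode %s, %s\n", x$name,
              length(x$patterns), x$mode,
              if (x$case_insensitive) "case-insensitive" else "case-sensitive"))
  invisible(x)
}

#' Read a lexicon file
#'
#' One pattern per line; `#` starts a comment. Directive lines of the form
#' `#! key: value` declare `name`, `mode` and `case_insensitive` in the file
#' header. A second whitespace-separated field of `word-boundary` or
#' `substring-stem` on a pattern line overrides the mode for that pattern.
#'
#' @param path lexicon file path.
#' @return a `dili_lexicon`.
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  name <- sub("\\.[^.]*$", "", basename(path))
  mode <- "substring-stem"
  ci <- TRUE
  pats <- character(0)
  pmode <- character(0)
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (startsWith(ln, "#!")) {
      kv <- strsplit(sub("^#!\\s*", "", ln), ":", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = ":"))
      if (key == "name") name <- val
      if (key == "mode") mode <- val
      if (key == "case_insensitive") ci <- tolower(val) %in% c("true", "yes", "1")
      next
    }
    if (startsWith(ln, "#")) next
    fields <- strsplit(ln, "\t")[[1]]
    pats <- c(pats, trimws(fields[1]))
    pmode <- c(pmode, if (length(fields) > 1L && nzchar(trimws(fields[2]))) trimws(fields[2]) else NA_character_)
  }
  if (!mode %in% c("substring-stem", "word-boundary")) stopf("unknown lexicon mode: %s", mode)
  pmode[is.na(pmode)] <- mode
  lexicon(pats, mode = mode, case_insensitive = ci, name = name, pattern_mode = pmode)
}

#' Write a lexicon file
#'
#' @param lex a `dili_lexicon`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(sprintf("#! name: %s", lex$name),
               sprintf("#! mode: %s", lex$mode),
               sprintf("#! case_insensitive: %s", tolower(as.character(lex$case_insensitive)))),
             con, useBytes = TRUE)
  lines <- ifelse(lex$pattern_mode == lex$mode, lex$patterns,
                  paste(lex$patterns, lex$pattern_mode, sep = "\t"))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Match a lexicon against sentence text
#'
#' @param text character vector of sentences.
#' @param lex a `dili_lexicon`.
#' @return logical vector: does any pattern match each sentence?
#' @export
lexicon_match <- function(text, lex) {
  stopifnot(inherits(lex, "dili_lexicon"))
  hay <- squish(text)
  if (lex$case_insensitive) hay <- tolower(hay)
  out <- rep(FALSE, length(hay))
  for (i in seq_along(lex$patterns)) {
    pat <- if (lex$case_insensitive) tolower(lex$patterns[i]) else lex$patterns[i]
    if (lex$pattern_mode[i] == "substring-stem") {
      out <- out | grepl(pat, hay, fixed = TRUE)
    } else {
      rx <- paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", pat), "\\b")
      out <- out | grepl(rx, hay, perl = TRUE)
    }
    if (all(out)) break
  }
  out
}

# match multi-token lexicon patterns against a token sequence; returns an
# IOB tag vector. Greedy longest-match scan; a stem-mode pattern token
# matches a word token by prefix, word-boundary by equality; tokens with
# internal "/" are additionally matched part-wise (so "SGOT/AST" matches the
# single-token pattern "SGOT").
match_term_spans <- function(tokens, lex) {
  n <- length(tokens)
  tags <- rep("O", n)
  if (!n) return(tags)
  toks <- if (lex$case_insensitive) tolower(tokens) else tokens
  pat_toks <- lapply(if (lex$case_insensitive) tolower(lex$patterns) else lex$patterns,
                     function(p) strsplit(p, "\\s+")[[1]])
  ord <- order(-lengths(pat_toks))
  has_slash <- grepl("/", toks, fixed = TRUE)
  parts_list <- as.list(toks)
  if (any(has_slash)) {
    parts_list[has_slash] <- Map(function(t, p) unique(c(t, p)), toks[has_slash],
                                 strsplit(toks[has_slash], "/", fixed = TRUE))
  }
  token_hits <- function(i2, ptok, stem) {
    parts <- parts_list[[i2]]
    if (stem) any(startsWith(parts, ptok)) else any(parts == ptok)
  }
  i <- 1L
  while (i <= n) {
    matched <- 0L
    for (k in ord) {
      pt <- pat_toks[[k]]
      L <- length(pt)
      if (i + L - 1L > n) next
      stem <- lex$pattern_mode[k] == "substring-stem"
      ok <- TRUE
      for (j in seq_len(L)) {
        if (!token_hits(i + j - 1L, pt[j], stem)) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        matched <- L
        break
      }
    }
    if (matched > 0L) {
      tags[i] <- "B-LIVER"
      if (matched > 1L) tags[(i + 1L):(i + matched - 1L)] <- "I-LIVER"
      i <- i + matched
    } else {
      i <- i + 1L
    }
  }
  tags
}

lexicon_path <- function(file) {
  system.file("extdata", file, package = "dilitext", mustWork = TRUE)
}

#' Built-in lexicons
#'
#' `default_context_lexicon()`: broad liver-context stems for the
#' sentence-level string gate (any possible relation to liver: ADRs,
#' indications, contraindications, monitoring). `default_liver_terms()`:
#' token-level liver-term span patterns used by the lexicon tagger and the
#' synthetic generator. `default_dili_lexicon()`: DILI keyword terms for the
#' keyword baseline classifier. `default_adr_cue_lexicon()`: reporting-verb
#' cue phrases that identify attributable-ADR statements; with the liver
#' gate this forms an exact oracle on the synthetic corpus.
#'
#' @return a `dili_lexicon`.
#' @export
default_context_lexicon <- function() read_lexicon(lexicon_path("context_patterns.txt"))

#' @rdname default_context_lexicon
#' @export
default_liver_terms <- function() read_lexicon(lexicon_path("liver_terms.txt"))

#' @rdname default_context_lexicon
#' @export
default_dili_lexicon <- function() read_lexicon(lexicon_path("dili_keywords.txt"))

#' @rdname default_context_lexicon
#' @export
default_adr_cue_lexicon <- function() read_lexicon(lexicon_path("adr_cues.txt"))
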