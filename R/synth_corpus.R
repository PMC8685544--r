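#' Parameters for the synthetic labeling corpus generator
#'
#' Defaults emulate the class structure of a prescription-labeling
#' "Warnings and Precautions" corpus: roughly a quarter of documents carry a
#' hepatic-ADR warning, about 2% of all sentences are DILI-positive, and
#' about 70% of liver-mention sentences are DILI-negative frames
#' (contraindication, hepatic indication, laboratory monitoring) — the hard
#' cases that separate semantic models from keyword matching.
#'
#' @param n_docs number of documents.
#' @param sentences_min,sentences_max per-document sentence count, drawn
#'   uniformly from `sentences_min:sentences_max`.
#' @param doc_positive_prevalence probability that a document carries at
#'   least one attributable hepatic-ADR sentence.
#' @param liver_negative_frame_rate target share of liver-mention sentences
#'   that are DILI-negative frames (indication / contraindication /
#'   monitoring), in [0, 1).
#' @param dup_rate probability that a DILI-negative sentence is replaced by
#'   a verbatim copy of an earlier DILI-negative sentence (labeling
#'   boilerplate), in [0, 1).
#' @param n_positive_docs optional exact number of positive documents,
#'   overriding the Bernoulli draw.
#' @param unseen_variants inject hepatic term variants and abbreviations
#'   (ASAT, ALAT, transaminitis, icterus, ...) that are absent from the
#'   shipped lexicon files, reproducing the fixed-dictionary failure mode.
#' @param seed integer seed; the same parameters and seed yield a
#'   byte-identical corpus.
#' @return an object of class `synth_params`.
#' @export
synth_params <- function(n_docs = 200,
                         sentences_min = 15, sentences_max = 45,
                         doc_positive_prevalence = 0.27,
                         liver_negative_frame_rate = 0.7,
                         dup_rate = 0.05,
                         n_positive_docs = NULL,
                         unseen_variants = FALSE,
                         seed = 1L) {
  if (!is_count(n_docs)) stopf("n_docs must be a positive integer")
  if (!is_count(sentences_min, 3) || !is_count(sentences_max, sentences_min)) {
    stopf("need 3 <= sentences_min <= sentences_max")
  }
  if (!is_prob(doc_positive_prevalence)) stopf("doc_positive_prevalence must be in [0,1]")
  if (!is_prob(liver_negative_frame_rate) || liver_negative_frame_rate >= 1) {
    stopf("liver_negative_frame_rate must be in [0,1)")
  }
  if (!is_prob(dup_rate) || dup_rate >= 1) stopf("dup_rate must be in [0,1)")
  if (!is.null(n_positive_docs)) {
    if (!is_count(n_positive_docs, 0) || n_positive_docs > n_docs) {
      stopf("n_positive_docs must be an integer in [0, n_docs]")
    }
    if (doc_positive_prevalence == 0 && n_positive_docs > 0) {
      stopf("degenerate parameters: prevalence 0 with a requested positive count")
    }
  }
  structure(list(n_docs = as.integer(n_docs),
                 sentences_min = as.integer(sentences_min),
                 sentences_max = as.integer(sentences_max),
                 doc_positive_prevalence = doc_positive_prevalence,
                 liver_negative_frame_rate = liver_negative_frame_rate,
                 dup_rate = dup_rate,
                 n_positive_docs = n_positive_docs,
                 unseen_variants = isTRUE(unseen_variants),
                 seed = as.integer(seed)),
            class = "synth_params")
}

# ---- template grammar -------------------------------------------------------

SYNTH_FRAMES <- c("ADR_HEPATIC", "CONTRAINDICATION", "INDICATION", "MONITORING", "NONLIVER")

# attributable hepatic-ADR terms; every one is covered by the shipped
# liver-term and DILI-keyword lexicons
ADR_TERMS <- c("hepatotoxicity", "hepatic toxicity", "hepatic failure",
               "liver failure", "hepatitis", "fulminant hepatitis",
               "hepatic necrosis", "hepatocellular injury", "liver injury",
               "jaundice", "hyperbilirubinemia")

# variants/abbreviations deliberately absent from the shipped lexicons
UNSEEN_ADR_TERMS <- c("transaminitis", "icterus", "hepatocellular damage")
UNSEEN_ENZYMES <- c("ASAT", "ALAT")

ENZYMES <- c("ALT", "AST", "SGPT", "SGOT", "SGOT/AST", "SGPT/ALT",
             "alkaline phosphatase", "transaminases", "aminotransferases")

NONLIVER_ADRS <- c("rash", "nausea", "dizziness", "headache", "anaphylaxis",
                   "neutropenia", "peripheral edema", "somnolence",
                   "diarrhea", "QT prolongation")

NONLIVER_CONDS <- c("major depressive disorder", "type 2 diabetes mellitus",
                    "hypertension", "community-acquired pneumonia",
                    "rheumatoid arthritis", "partial-onset seizures")

DOSES <- c("2.5", "5", "7.5", "10", "12.5", "20", "50", "100")

synth_drug_names <- function(n = 60) sprintf("DRUG-%03d", seq_len(n))

cap_first <- function(x) {
  paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
}

# each template is a function(env) -> sentence text (terminated by ".")
synth_templates <- function() {
  list(
    ADR_HEPATIC = list(
      function(e) sprintf("%s including %s resulting in transplantation or death have been reported in patients treated with %s.",
                          cap_first(e$term), e$term2, e$drug),
      function(e) sprintf("Severe %s, sometimes fatal, has been reported during treatment with %s.",
                          e$term, e$drug),
      function(e) sprintf("Cases of %s have been reported in postmarketing experience with %s.",
                          e$term, e$drug),
      function(e) sprintf("%s and %s have occurred in patients receiving %s.",
                          cap_first(e$term), e$term2, e$drug),
      function(e) sprintf("Fatal %s was observed in clinical trials of %s.",
                          e$term, e$drug)
    ),
    CONTRAINDICATION = list(
      function(e) sprintf("%s should not be used by patients with severe hepatic impairment.", e$drug),
      function(e) sprintf("%s is contraindicated in patients with moderate or severe hepatic impairment.", e$drug),
      function(e) sprintf("Use of %s is not recommended in patients with pre-existing liver disease.", e$drug),
      function(e) sprintf("Dose reduction of %s is required in patients with hepatic insufficiency.", e$drug)
    ),
    INDICATION = list(
      function(e) sprintf("%s is indicated for the treatment of chronic hepatitis B.", e$drug),
      function(e) sprintf("%s is indicated for the treatment of chronic hepatitis C in adults.", e$drug),
      function(e) sprintf("%s is indicated for the treatment of chronic hepatitis B in patients with compensated liver disease.", e$drug)
    ),
    MONITORING = list(
      function(e) sprintf("Monitor serum %s periodically during treatment with %s.", e$enzyme, e$drug),
      function(e) sprintf("Perform liver function tests at baseline and monthly thereafter."),
      function(e) sprintf("Measure %s and bilirubin levels before initiating %s.", e$enzyme, e$drug),
      function(e) sprintf("Periodic monitoring of %s is recommended in patients receiving %s.", e$enzyme, e$drug)
    ),
    NONLIVER = list(
      # non-liver ADR statements mirror the hepatic-ADR cue phrasing, as in
      # real labeling boilerplate, so reporting cues are class-neutral
      function(e) sprintf("%s has been reported in patients treated with %s.", cap_first(e$adr), e$drug),
      function(e) sprintf("Severe %s, sometimes fatal, has been reported during treatment with %s.", e$adr, e$drug),
      function(e) sprintf("Cases of %s have been reported in postmarketing experience with %s.", e$adr, e$drug),
      function(e) sprintf("%s and %s have occurred in patients receiving %s.", cap_first(e$adr), e$adr2, e$drug),
      function(e) sprintf("Fatal %s was observed in clinical trials of %s.", e$adr, e$drug),
      function(e) "Treat all infections due to Group A beta-hemolytic streptococci for at least 10 days.",
      function(e) sprintf("%s is indicated for the treatment of %s.", e$drug, e$cond),
      function(e) sprintf("Doses of %s mg were studied in clinical trials.", e$dose),
      function(e) sprintf("The most common adverse reactions were %s and %s.", e$adr, e$adr2),
      function(e) sprintf("Advise patients to avoid driving until the effect of %s is known.", e$drug),
      function(e) sprintf("%s may cause %s in elderly patients.", e$drug, e$adr),
      function(e) "Monitor blood pressure regularly during therapy."
    )
  )
}

# realize one sentence of a given frame; returns its text
fill_template <- function(frame, templates, drugs, adr_terms, enzymes) {
  tpl <- templates[[frame]]
  f <- tpl[[sample.int(length(tpl), 1L)]]
  terms <- sample(adr_terms, min(2L, length(adr_terms)))
  adrs <- sample(NONLIVER_ADRS, 2L)
  env <- list(drug = sample(drugs, 1L),
              term = terms[1L], term2 = terms[length(terms)],
              enzyme = sample(enzymes, 1L),
              adr = adrs[1L], adr2 = adrs[2L],
              cond = sample(NONLIVER_CONDS, 1L),
              dose = sample(DOSES, 1L))
  f(env)
}

#' Generate a synthetic labeling corpus with full ground truth
#'
#' Builds labeling-style documents from a template grammar in five sentence
#' frames — attributable hepatic ADR, hepatic contraindication, hepatic
#' indication, laboratory monitoring, and non-liver content — together with
#' a ground-truth ledger carrying token-level IOB tags over
#' `{O, B-LIVER, I-LIVER}`, sentence-level DILI and liver-context labels,
#' and document-level DILI labels (the OR of the sentence labels).
#'
#' @param params a [synth_params()] object.
#' @return a list with elements `documents` (document data frame as in
#'   [read_documents()]) and `ledger` (per-sentence data frame with columns
#'   `doc_id`, `index`, `frame`, `dili_label`, `liver_label`, `text` and
#'   list columns `tokens`, `tags`). The ledger carries attributes
#'   `n_unique` (distinct normalized sentence count), `frame_draws` (frame
#'   counts recorded at draw time) and `params`.
#' @export
generate_corpus <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  templates <- synth_templates()
  drugs <- synth_drug_names()
  adr_terms <- ADR_TERMS
  enzymes <- ENZYMES
  term_lex <- generator_term_lexicon(params$unseen_variants)
  if (params$unseen_variants) {
    adr_terms <- c(adr_terms, UNSEEN_ADR_TERMS)
    enzymes <- c(enzymes, UNSEEN_ENZYMES)
  }

  # expected DILI-positive sentence fraction under the defaults, used to
  # derive the per-sentence liver-negative frame probability that hits the
  # requested share of negatives among liver-mention sentences
  mean_sent <- (params$sentences_min + params$sentences_max) / 2
  mean_pos <- 2 # E[positives per positive document], sampled from 1:3
  f_pos <- params$doc_positive_prevalence * mean_pos / mean_sent
  r <- params$liver_negative_frame_rate
  g <- if (r > 0) f_pos * r / (1 - r) else 0
  if (f_pos <= 0 && r > 0) g <- 0.04 # liver-negative frames still wanted when prevalence is 0
  q <- min(0.95, g / max(1 - f_pos, 1e-9))

  with_seed(params$seed, {
    n <- params$n_docs
    doc_ids <- sprintf("SYN-%05d", seq_len(n))
    pos_doc <- if (!is.null(params$n_positive_docs)) {
      flags <- rep(FALSE, n)
      if (params$n_positive_docs > 0) flags[sample.int(n, params$n_positive_docs)] <- TRUE
      flags
    } else {
      stats::runif(n) < params$doc_positive_prevalence
    }
    rows <- vector("list", n)
    for (d in seq_len(n)) {
      n_sent <- sample(params$sentences_min:params$sentences_max, 1L)
      k_pos <- if (pos_doc[d]) sample.int(3L, 1L) else 0L
      frame <- rep(NA_character_, n_sent)
      if (k_pos > 0L) frame[sample.int(n_sent, k_pos)] <- "ADR_HEPATIC"
      rest <- which(is.na(frame))
      is_ln <- stats::runif(length(rest)) < q
      frame[rest[is_ln]] <- sample(c("CONTRAINDICATION", "INDICATION", "MONITORING"),
                                   sum(is_ln), replace = TRUE)
      frame[rest[!is_ln]] <- "NONLIVER"
      text <- vapply(frame, fill_template, character(1),
                     templates = templates, drugs = drugs,
                     adr_terms = adr_terms, enzymes = enzymes)
      rows[[d]] <- data.frame(doc_id = doc_ids[d], index = seq_len(n_sent),
                              frame = frame, text = text,
                              stringsAsFactors = FALSE)
    }
    ledger <- do.call(rbind, rows)
    rownames(ledger) <- NULL

    # boilerplate duplication: overwrite DILI-negative sentences with copies
    # of earlier DILI-negative sentences so document labels are untouched
    if (params$dup_rate > 0 && nrow(ledger) > 1L) {
      neg <- which(ledger$frame != "ADR_HEPATIC")
      if (length(neg) > 1L) {
        dup <- neg[-1L][stats::runif(length(neg) - 1L) < params$dup_rate]
        for (i in dup) {
          src <- neg[neg < i]
          j <- src[sample.int(length(src), 1L)]
          ledger$frame[i] <- ledger$frame[j]
          ledger$text[i] <- ledger$text[j]
        }
      }
    }

    frame_draws <- table(factor(ledger$frame, levels = SYNTH_FRAMES))
    ledger$dili_label <- as.integer(ledger$frame == "ADR_HEPATIC")
    ledger$liver_label <- as.integer(ledger$frame != "NONLIVER")
    toks <- tokenize_words(ledger$text)
    ledger$tokens <- I(toks)
    # cheap stem pre-filter: only sentences that can contain a liver term go
    # through the span matcher; everything else is all-O
    maybe <- grepl(paste0("hepat|liver|jaund|bilirub|transamin|aminotransf|",
                          "phosphatase|cholestat|sgot|sgpt|ggt|icterus|asat|",
                          "alat|\\balt\\b|\\bast\\b|\\balp\\b"),
                   tolower(ledger$text), perl = TRUE)
    tags <- lapply(lengths(toks), function(n) rep("O", n))
    tags[maybe] <- lapply(toks[maybe], match_term_spans, lex = term_lex)
    ledger$tags <- I(tags)

    doc_text <- vapply(split(ledger$text, ledger$doc_id)[doc_ids],
                       paste, character(1), collapse = " ")
    documents <- data.frame(doc_id = doc_ids, agency = "SYNTH",
                            section = "Warnings and Precautions",
                            text = unname(doc_text),
                            dili_label = as.integer(pos_doc),
                            stringsAsFactors = FALSE)
    attr(ledger, "n_unique") <- length(unique(squish(ledger$text)))
    attr(ledger, "frame_draws") <- frame_draws
    attr(ledger, "params") <- params
    list(documents = documents, ledger = ledger)
  })
}

# the span inventory the generator tags with; extends the shipped liver
# terms with the deliberately-unseen variants when requested
generator_term_lexicon <- function(unseen_variants = FALSE) {
  lex <- default_liver_terms()
  if (!unseen_variants) return(lex)
  extra <- c(UNSEEN_ADR_TERMS, UNSEEN_ENZYMES)
  lexicon(c(lex$patterns, extra),
          mode = lex$mode, case_insensitive = lex$case_insensitive,
          name = paste0(lex$name, "+variants"),
          pattern_mode = c(lex$pattern_mode,
                           ifelse(nchar(extra) <= 4, "word-boundary", "substring-stem")))
}

#' Summarize a ground-truth ledger
#'
#' @param ledger ledger data frame from [generate_corpus()].
#' @return a list with total/positive/negative sentence counts, liver
#'   context counts, the per-frame count table and the distinct sentence
#'   count.
#' @export
corpus_summary <- function(ledger) {
  if (!nrow(ledger)) stopf("empty ledger")
  frames <- table(factor(ledger$frame, levels = SYNTH_FRAMES))
  list(
    n_sentences = nrow(ledger),
    dili_positive = sum(ledger$dili_label == 1L),
    dili_negative = sum(ledger$dili_label == 0L),
    liver_context = sum(ledger$liver_label == 1L),
    liver_context_negative = sum(ledger$liver_label == 1L & ledger$dili_label == 0L),
    frames = frames,
    n_unique = length(unique(squish(ledger$text)))
  )
}

#' Ledger token annotations as CoNLL-style sequences
#'
#' @param ledger ledger data frame from [generate_corpus()].
#' @return a list of sequences (`tokens`, `tags`) suitable for
#'   [write_conll()] and the taggers.
#' @export
ledger_to_conll <- function(ledger) {
  lapply(seq_len(nrow(ledger)), function(i) {
    list(tokens = ledger$tokens[[i]], tags = ledger$tags[[i]])
  })
}

#' Worked example sentences
#'
#' Three fixed labeling sentences illustrating the three cases the pipeline
#' must separate: an attributable hepatic ADR (DILI-positive), a hepatic
#' contraindication (liver context but DILI-negative), and a non-liver
#' instruction.
#'
#' @return data frame with columns `text`, `dili_label`, `liver_label`.
#' @export
example_sentences <- function() {
  path <- system.file("extdata", "example_sentences.jsonl", package = "dilitext",
                      mustWork = TRUE)
  recs <- lapply(readLines(path, warn = FALSE), jsonlite::fromJSON)
  data.frame(text = vapply(recs, `[[`, character(1), "text"),
             dili_label = vapply(recs, `[[`, integer(1), "dili_label"),
             liver_label = vapply(recs, `[[`, integer(1), "liver_label"),
             stringsAsFactors = FALSE)
}
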