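# Shared fixtures, built once per test run. Sizes are kept small; the
# full-scale runs live in the acceptance tests.

fx <- new.env()

# 60-document default-condition corpus (~1,800 sentences)
fx_corpus <- function() {
  if (is.null(fx$corpus)) fx$corpus <- generate_corpus(synth_params(n_docs = 60, seed = 101))
  fx$corpus
}

# liver-gated labeled sentences from the fixture corpus
fx_gated <- function() {
  if (is.null(fx$gated)) {
    led <- fx_corpus()$ledger
    fx$gated <- led[string_gate(led$text), , drop = FALSE]
  }
  fx$gated
}

# sentence classifier trained on the gated fixture sentences
fx_classifier <- function() {
  if (is.null(fx$clf)) {
    g <- fx_gated()
    fx$clf <- train_classifier(g$text, g$dili_label, seed = 101)
  }
  fx$clf
}

# the lexicon-tagger oracle
fx_tagger <- function() {
  if (is.null(fx$tagger)) fx$tagger <- train_tagger(backend = "lexicon")
  fx$tagger
}

# random valid IOB sequence for round-trip tests
random_iob_seq <- function(n_tokens) {
  tokens <- paste0("tok", sample.int(500, n_tokens, replace = TRUE))
  tags <- character(n_tokens)
  prev_liver <- FALSE
  for (i in seq_len(n_tokens)) {
    tags[i] <- if (prev_liver) {
      sample(c("O", "B-LIVER", "I-LIVER"), 1, prob = c(0.6, 0.2, 0.2))
    } else {
      sample(c("O", "B-LIVER"), 1, prob = c(0.8, 0.2))
    }
    prev_liver <- tags[i] %in% c("B-LIVER", "I-LIVER")
  }
  list(tokens = tokens, tags = tags)
}
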