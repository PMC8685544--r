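test_that("the keyword baseline matches dictionary semantics, context-blind", {
  ex <- example_sentences()
  # the hepatic-impairment contraindication is the characteristic false positive
  expect_identical(keyword_classify(ex$text), c(1L, 1L, 0L))
  expect_identical(keyword_classify("No adverse events were reported."), 0L)
  # monotone in the lexicon
  lex <- default_dili_lexicon()
  bigger <- lexicon(c(lex$patterns, "cholestasis"), mode = lex$mode,
                    pattern_mode = c(lex$pattern_mode, "substring-stem"))
  texts <- fx_gated()$text
  expect_true(all(keyword_classify(texts, bigger)[keyword_classify(texts, lex) == 1L] == 1L))
  # word-order blind for single-token matches
  s <- "jaundice severe was noted"
  expect_identical(keyword_classify(s), keyword_classify("severe noted was jaundice"))
})

test_that("classifier training is seed-deterministic with consistent thresholding", {
  g <- fx_gated()
  probe <- g$text[seq(1, nrow(g), by = 7)]
  a <- train_classifier(g$text, g$dili_label, seed = 5)
  b <- train_classifier(g$text, g$dili_label, seed = 5)
  pa <- predict(a, probe)
  expect_identical(pa, predict(b, probe))
  expect_true(all(pa$score >= 0 & pa$score <= 1))
  expect_identical(pa$label, as.integer(pa$score >= 0.5))
  expect_error(train_classifier(g$text, rep(1L, nrow(g))), "both classes")
  expect_error(train_classifier(character(0), integer(0)), "empty")
})

test_that("the solvable-regime classifier is accurate in cross-validation", {
  g <- fx_gated()
  cv <- repeated_cv(g$text, g$dili_label, k = 5, reps = 2, seed = 13)
  acc <- cv$summary$mean[cv$summary$metric == "accuracy"]
  expect_gte(acc, 0.95)
})

test_that("label shuffling drives held-out accuracy to the majority prior", {
  g <- fx_gated()
  majority <- max(mean(g$dili_label), 1 - mean(g$dili_label))
  accs <- numeric(30)
  set.seed(99)
  for (i in seq_along(accs)) {
    y <- sample(g$dili_label)
    te <- seq_len(nrow(g)) %% 5 == 0
    clf <- train_classifier(g$text[!te], y[!te], seed = i)
    accs[i] <- mean(predict(clf, g$text[te])$label == y[te])
  }
  expect_lte(abs(mean(accs) - majority), 3 * sd(accs))
})

test_that("class-weight oversampling is binomially calibrated", {
  df <- data.frame(text = sprintf("s%03d", 1:100),
                   dili_label = rep(c(0L, 1L), c(90, 10)))
  pos <- vapply(1:200, function(s) sum(oversample(df, seed = s)$dili_label), numeric(1))
  expect_identical(length(unique(vapply(1:3, function(i) sum(oversample(df, seed = 42)$dili_label), numeric(1)))), 1L)
  # positive count ~ Binomial(100, 0.5): mean over 200 seeds within 3 sd of 50
  expect_lte(abs(mean(pos) - 50), 3 * 5 / sqrt(200))
  expect_identical(nrow(oversample(df, seed = 1)), nrow(df))
  expect_error(oversample(df[df$dili_label == 0L, ]), "both classes")
})

test_that("occlusion attributions are additive on the link scale", {
  g <- fx_gated()
  clf <- fx_classifier()
  beta <- as.matrix(stats::coef(clf$fit, s = clf$lambda))
  for (text in g$text[c(1, 8, 21, 33, 55)]) {
    at <- token_attribution(clf, text, scale = "link")
    tokens <- tokenize_words(text)[[1]]
    for (i in seq_along(tokens)) {
      masked <- tokens
      masked[i] <- "xxunkxx"
      d <- dilitext:::ngram_matrix(dilitext:::ngram_features(paste(tokens, collapse = " ")), clf$vocab) -
        dilitext:::ngram_matrix(dilitext:::ngram_features(paste(masked, collapse = " ")), clf$vocab)
      expect_lt(abs(at[[i]] - sum(d * beta[-1, ])), 1e-6)
    }
  }
})

test_that("out-of-vocabulary tokens get exactly zero attribution", {
  clf <- fx_classifier()
  at <- token_attribution(clf, "zzzunseenzzz hepatotoxicity was observed")
  expect_identical(unname(at["zzzunseenzzz"]), 0)
  expect_error(token_attribution(clf, ""), "empty")
})

test_that("the planted hepatic-ADR term drives positive predictions", {
  corpus <- generate_corpus(synth_params(n_docs = 250, seed = 42))
  led <- corpus$ledger
  # ungated regime with class-weight oversampling (cue phrasing is shared
  # with non-liver ADR statements, so the hepatic term carries the signal)
  ov <- oversample(led, seed = 42)
  clf <- train_classifier(ov$text, ov$dili_label, seed = 42)
  adr <- led[led$dili_label == 1L, ]
  adr <- adr[seq_len(min(100, nrow(adr))), ]
  top_in_span <- logical(nrow(adr))
  pos_span <- logical(nrow(adr))
  for (i in seq_len(nrow(adr))) {
    at <- token_attribution(clf, adr$text[i])
    span <- adr$tags[[i]] != "O"
    top_in_span[i] <- span[which.max(at)]
    pos_span[i] <- max(at[span]) > 0
  }
  expect_true(all(pos_span))
  expect_gte(mean(top_in_span), 0.9)

  # a well-trained liver-context model gives "hepatitis" no positive push
  # inside chronic-hepatitis indication phrases
  gclf <- train_classifier(led$text[string_gate(led$text)],
                           led$dili_label[string_gate(led$text)], seed = 42)
  ind <- led[led$frame == "INDICATION", ]
  ind <- ind[seq_len(min(50, nrow(ind))), ]
  for (i in seq_len(nrow(ind))) {
    at <- token_attribution(gclf, ind$text[i])
    hep <- tolower(names(at)) == "hepatitis"
    if (any(hep)) expect_lte(max(at[hep]), 1e-9)
  }
})
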