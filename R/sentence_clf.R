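#' Keyword baseline classifier for DILI sentences
#'
#' Labels a sentence DILI-positive iff any DILI keyword matches, with no
#' context reasoning — the conventional dictionary approach. Its
#' characteristic failure mode is firing on hepatic terms inside
#' contraindications ("patients with severe hepatic impairment") and
#' indications ("treatment of chronic hepatitis B").
#'
#' @param text character vector of sentences.
#' @param lex DILI keyword lexicon; defaults to [default_dili_lexicon()].
#' @return integer vector of 0/1 labels.
#' @export
keyword_classify <- function(text, lex = default_dili_lexicon()) {
  as.integer(lexicon_match(text, lex))
}

# ---- featurization (uncased bag of 1-2 grams) -------------------------------

ngram_features <- function(text) {
  toks <- tokenize_words(tolower(text))
  lapply(toks, function(tk) {
    tk <- tk[grepl("[a-z0-9]", tk)] # drop bare punctuation tokens
    if (!length(tk)) return(character(0))
    uni <- tk
    bi <- if (length(tk) > 1L) paste(tk[-length(tk)], tk[-1L], sep = "_") else character(0)
    c(uni, bi)
  })
}

ngram_matrix <- function(feat_list, vocab) {
  idx <- lapply(feat_list, function(f) {
    m <- match(f, vocab)
    m[!is.na(m)]
  })
  rows <- rep(seq_along(idx), lengths(idx))
  cols <- unlist(idx, use.names = FALSE)
  Matrix::sparseMatrix(i = rows, j = cols, x = 1,
                       dims = c(length(idx), length(vocab)),
                       dimnames = list(NULL, vocab))
}

#' Train a binary DILI sentence classifier
#'
#' Backends: `"linear"`, a ridge-logistic bag-of-1-2-grams model fitted with
#' glmnet (uncased, deterministic given the seed); and `"keyword"`, the
#' dictionary baseline wrapped in the same interface. The decision
#' threshold is fixed at 0.5: the predicted label is 1 iff the score is at
#' least 0.5.
#'
#' @param text character vector of training sentences.
#' @param labels 0/1 vector of DILI labels (both classes required).
#' @param backend `"linear"` or `"keyword"`.
#' @param hyperparams list; for `"linear"`: `lambda` (default 0.01) and
#'   `alpha` (default 0, ridge).
#' @param lexicon keyword lexicon for the keyword backend.
#' @param seed integer seed recorded with the model.
#' @return a classifier with a `predict()` method returning a data frame of
#'   `label` and `score`.
#' @export
train_classifier <- function(text = NULL, labels = NULL,
                             backend = c("linear", "keyword"),
                             hyperparams = list(),
                             lexicon = default_dili_lexicon(), seed = 1L) {
  backend <- match.arg(backend)
  if (backend == "keyword") {
    return(structure(list(backend = "keyword", lexicon = lexicon, seed = seed),
                     class = c("keyword_clf", "dili_clf")))
  }
  if (is.null(text) || !length(text)) stopf("empty training set")
  labels <- as.integer(labels)
  if (length(labels) != length(text)) stopf("text and labels lengths differ")
  if (length(unique(labels)) < 2L) stopf("training labels must contain both classes")
  feats <- ngram_features(text)
  vocab <- sort(unique(unlist(feats)))
  X <- ngram_matrix(feats, vocab)
  lambda <- hyperparams$lambda %||% 0.01
  alpha <- hyperparams$alpha %||% 0
  fit <- with_seed(as.integer(seed),
                   glmnet::glmnet(X, factor(labels, levels = c(0L, 1L)),
                                  family = "binomial", alpha = alpha,
                                  standardize = FALSE,
                                  lambda = sort(unique(c(lambda, lambda * c(10, 100))),
                                                decreasing = TRUE)))
  structure(list(backend = "linear", fit = fit, vocab = vocab,
                 lambda = lambda, seed = seed),
            class = c("linear_clf", "dili_clf"))
}

#' @export
predict.linear_clf <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  X <- ngram_matrix(ngram_features(newdata), object$vocab)
  s <- as.numeric(stats::predict(object$fit, newx = X, s = object$lambda,
                                 type = type))
  if (type == "link") {
    return(data.frame(label = as.integer(s >= 0), score = s))
  }
  data.frame(label = as.integer(s >= 0.5), score = s)
}

#' @export
predict.keyword_clf <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  lab <- keyword_classify(newdata, object$lexicon)
  score <- as.numeric(lab)
  if (type == "link") score <- ifelse(lab == 1L, 1, -1)
  data.frame(label = lab, score = score)
}

#' Class-weight oversampling
#'
#' Draws `nrow(data)` rows with replacement with selection probability
#' inversely proportional to class frequency, so the expected class balance
#' of the resample is 1:1 regardless of the input imbalance.
#'
#' @param data data frame containing the label column.
#' @param label_col name of the 0/1 label column (default `"dili_label"`).
#' @param seed integer seed; the same seed reproduces the same resample.
#' @return the resampled data frame (same number of rows).
#' @export
oversample <- function(data, label_col = "dili_label", seed = 1L) {
  y <- data[[label_col]]
  if (is.null(y)) stopf("missing label column: %s", label_col)
  tab <- table(y)
  if (length(tab) < 2L) stopf("oversampling needs both classes present")
  w <- 1 / as.numeric(tab[as.character(y)])
  idx <- with_seed(as.integer(seed),
                   sample.int(nrow(data), nrow(data), replace = TRUE, prob = w))
  out <- data[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Occlusion-based token attribution
#'
#' Quantifies each token's contribution to a classifier's prediction as
#' `score(sentence) - score(sentence with the token masked)`, where masking
#' replaces the token with an out-of-vocabulary placeholder. Positive
#' values push the prediction toward DILI-positive. For the linear
#' bag-of-ngrams backend on the link (pre-sigmoid) scale this equals the
#' summed coefficients of the n-grams the token participates in.
#'
#' @param clf a trained classifier from [train_classifier()].
#' @param text a single sentence.
#' @param scale `"response"` (probability scale) or `"link"` (pre-sigmoid).
#' @return named numeric vector of per-token attributions.
#' @export
token_attribution <- function(clf, text, scale = c("response", "link")) {
  scale <- match.arg(scale)
  stopifnot(length(text) == 1L)
  tokens <- tokenize_words(text)[[1]]
  if (!length(tokens)) stopf("empty sentence")
  variants <- vapply(seq_along(tokens), function(i) {
    masked <- tokens
    masked[i] <- "xxunkxx"
    paste(masked, collapse = " ")
  }, character(1))
  base_text <- paste(tokens, collapse = " ")
  preds <- predict(clf, c(base_text, variants), type = scale)$score
  out <- preds[1L] - preds[-1L]
  names(out) <- tokens
  out
}
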