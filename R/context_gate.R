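#' String-pattern liver-context gate
#'
#' Stage one of the hybrid pipeline: a sentence passes the gate iff at least
#' one pattern of the context lexicon matches. Broad stems keep every
#' sentence with any possible relation to liver — ADRs, indications,
#' contraindications, monitoring — so downstream classification sees a
#' balanced, on-topic subset without losing positives.
#'
#' @param text character vector of sentences.
#' @param lex context lexicon; defaults to [default_context_lexicon()].
#' @return logical vector (`TRUE` = liver-related).
#' @export
string_gate <- function(text, lex = default_context_lexicon()) {
  lexicon_match(text, lex)
}

#' Token-score liver-context gate
#'
#' A sentence is liver-related iff at least one token's argmax tag is a
#' liver tag. Accepts either a character vector of IOB tags or a numeric
#' matrix of per-token tag scores (rows = tokens, columns = the tagset in
#' [iob_tagset()] order, `O` first). Argmax ties break toward the lowest
#' column index, i.e. toward `O`.
#'
#' @param tags_or_scores character tag vector or numeric score matrix.
#' @param liver_tags tag names counting as liver context.
#' @return logical scalar.
#' @export
ner_gate <- function(tags_or_scores, liver_tags = LIVER_TAGS) {
  x <- tags_or_scores
  if (is.character(x)) {
    if (!length(x)) stopf("ner_gate needs at least one token")
    bad <- setdiff(unique(x), IOB_TAGSET)
    if (length(bad)) stopf("tag outside tagset: %s", paste(bad, collapse = ", "))
    return(any(x %in% liver_tags))
  }
  if (!is.matrix(x) || !is.numeric(x)) stopf("expected character tags or a numeric score matrix")
  if (ncol(x) != length(IOB_TAGSET)) {
    stopf("score matrix must have %d columns (tagset arity), got %d",
          length(IOB_TAGSET), ncol(x))
  }
  if (!nrow(x)) stopf("ner_gate needs at least one token")
  if (any(!is.finite(x))) stopf("scores must be finite")
  am <- max.col(x, ties.method = "first")
  any(IOB_TAGSET[am] %in% liver_tags)
}

#' The IOB tagset
#'
#' @return ordered character vector: `O`, `B-LIVER`, `I-LIVER` (index 1 =
#'   the outside tag, which argmax ties resolve to).
#' @export
iob_tagset <- function() IOB_TAGSET

# ---- taggers ----------------------------------------------------------------

#' Train a token-level liver tagger
#'
#' Two backends are available. `"lexicon"` is a deterministic dictionary
#' tagger: a token span is tagged `B-LIVER`/`I-LIVER` iff it matches a
#' liver-term pattern; no training is performed (it serves as the exact
#' oracle in the solvable synthetic regime). `"linear"` is a learnable
#' ridge-logistic tagger over per-token features (lower-cased identity,
#' padded character 3-grams, word shape, and neighbor identities/shapes)
#' fitted with glmnet; when a development set is supplied, the
#' regularization strength is chosen by token-level F1 on it (the analogue
#' of best-epoch checkpointing).
#'
#' @param train_seqs list of sequences (`tokens`, `tags`) for training
#'   (ignored by the lexicon backend).
#' @param dev_seqs optional development sequences for model selection.
#' @param backend `"lexicon"` or `"linear"`.
#' @param hyperparams list; for `"linear"`: `lambda` (fixed value or grid,
#'   default `c(0.1, 0.03, 0.01, 0.003)`), `alpha` (elastic-net mixing,
#'   default 0 = ridge). Observations are class-balance weighted.
#' @param lexicon liver-term lexicon for the lexicon backend.
#' @param seed integer seed (the fit itself is deterministic; the seed is
#'   recorded for run metadata).
#' @return a tagger object with a [predict_tags()] method.
#' @export
train_tagger <- function(train_seqs = NULL, dev_seqs = NULL,
                         backend = c("lexicon", "linear"),
                         hyperparams = list(), lexicon = default_liver_terms(),
                         seed = 1L) {
  backend <- match.arg(backend)
  if (backend == "lexicon") {
    return(structure(list(backend = "lexicon", lexicon = lexicon, seed = seed),
                     class = c("lexicon_tagger", "dili_tagger")))
  }
  if (is.null(train_seqs) || !length(train_seqs)) stopf("empty training set")
  y <- unlist(lapply(train_seqs, function(s) s$tags %in% LIVER_TAGS))
  if (length(unique(y)) < 2L) stopf("training tokens must contain both liver and non-liver tags")
  feats <- lapply(train_seqs, function(s) token_features(s$tokens))
  vocab <- sort(unique(unlist(feats)))
  X <- feature_matrix(feats, vocab)
  lambda_grid <- hyperparams$lambda %||% c(0.1, 0.03, 0.01, 0.003)
  alpha <- hyperparams$alpha %||% 0
  # class-balanced observation weights: liver tokens are rare (~1-2%), and
  # without reweighting the penalized fit collapses to the all-O solution
  w <- ifelse(y, 0.5 / mean(y), 0.5 / (1 - mean(y)))
  fit <- with_seed(as.integer(seed),
                   glmnet::glmnet(X, factor(y, levels = c(FALSE, TRUE)),
                                  family = "binomial", alpha = alpha,
                                  weights = w, standardize = FALSE,
                                  lambda = sort(c(lambda_grid, 0.3), decreasing = TRUE)))
  model <- structure(list(backend = "linear", fit = fit, vocab = vocab,
                          lambda = min(lambda_grid), seed = seed),
                     class = c("linear_tagger", "dili_tagger"))
  if (!is.null(dev_seqs) && length(lambda_grid) > 1L) {
    truth <- lapply(dev_seqs, `[[`, "tags")
    f1s <- vapply(lambda_grid, function(lm) {
      m <- model
      m$lambda <- lm
      pred <- predict_tags(m, lapply(dev_seqs, `[[`, "tokens"))
      token_metrics(pred, truth)$f1
    }, numeric(1))
    model$lambda <- lambda_grid[which.max(f1s)]
  }
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-token feature strings: identity, char 3-grams, shape, neighbors
token_features <- function(tokens) {
  lo <- tolower(tokens)
  shape <- gsub("[A-Z]", "A", gsub("[a-z]", "a", gsub("[0-9]", "9", tokens)))
  shape <- gsub("(.)\\1+", "\\1", shape) # compress runs
  n <- length(tokens)
  prev <- c("<s>", lo[-n][seq_len(max(n - 1L, 0L))])
  nxt <- c(lo[-1L], "</s>")
  lapply(seq_len(n), function(i) {
    padded <- paste0("^", lo[i], "$")
    ng <- if (nchar(padded) >= 3L) {
      substring(padded, seq_len(nchar(padded) - 2L), seq(3L, nchar(padded)))
    } else padded
    c(paste0("w=", lo[i]), paste0("c3=", unique(ng)), paste0("sh=", shape[i]),
      paste0("p=", prev[i]), paste0("n=", nxt[i]))
  })
}

# list-of-token-feature-lists (per sentence) -> sparse indicator matrix
feature_matrix <- function(sent_feats, vocab) {
  flat <- unlist(sent_feats, recursive = FALSE, use.names = FALSE)
  idx <- lapply(flat, function(f) match(f, vocab))
  rows <- rep(seq_along(idx), lengths(idx))
  cols <- unlist(idx, use.names = FALSE)
  keep <- !is.na(cols)
  Matrix::sparseMatrix(i = rows[keep], j = cols[keep], x = 1,
                       dims = c(length(idx), length(vocab)))
}

#' Predict IOB tags or tag scores for token sequences
#'
#' @param model a tagger from [train_tagger()].
#' @param tokens_list a list of token character vectors (or a single one).
#' @param type `"tags"` for IOB tag vectors, `"scores"` for per-token score
#'   matrices over the tagset (rows sum to 1).
#' @return a list parallel to `tokens_list`.
#' @export
predict_tags <- function(model, tokens_list, type = c("tags", "scores")) {
  type <- match.arg(type)
  if (!is.list(tokens_list)) tokens_list <- list(tokens_list)
  UseMethod("predict_tags")
}

#' @export
predict_tags.lexicon_tagger <- function(model, tokens_list, type = c("tags", "scores")) {
  type <- match.arg(type)
  if (!is.list(tokens_list)) tokens_list <- list(tokens_list)
  lex <- model$lexicon
  # corpus-level pre-filter: a sentence can only contain a span if at least
  # one of its tokens matches some pattern token, so everything else is all-O
  lo_flat <- if (lex$case_insensitive) tolower(unlist(tokens_list)) else unlist(tokens_list)
  lens <- lengths(tokens_list)
  uniq <- unique(lo_flat)
  uniq_parts <- strsplit(uniq, "/", fixed = TRUE)
  pat_toks <- unlist(lapply(seq_along(lex$patterns), function(k) {
    p <- if (lex$case_insensitive) tolower(lex$patterns[k]) else lex$patterns[k]
    pt <- strsplit(p, "\\s+")[[1]]
    stats::setNames(pt, rep(lex$pattern_mode[k], length(pt)))
  }))
  cand <- rep(FALSE, length(uniq))
  for (j in seq_along(pat_toks)) {
    stem <- names(pat_toks)[j] == "substring-stem"
    hit <- if (stem) {
      startsWith(uniq, pat_toks[j]) |
        vapply(uniq_parts, function(p) any(startsWith(p, pat_toks[j])), logical(1))
    } else {
      uniq == pat_toks[j] | vapply(uniq_parts, function(p) any(p == pat_toks[j]), logical(1))
    }
    cand <- cand | hit
    if (all(cand)) break
  }
  flat_cand <- cand[match(lo_flat, uniq)]
  stops <- cumsum(lens)
  starts <- stops - lens + 1L
  tags <- vector("list", length(tokens_list))
  for (i in seq_along(tokens_list)) {
    if (lens[i] && any(flat_cand[starts[i]:stops[i]])) {
      tags[[i]] <- match_term_spans(tokens_list[[i]], lex)
    } else {
      tags[[i]] <- rep("O", lens[i])
    }
  }
  if (type == "tags") return(tags)
  lapply(tags, tags_to_scores)
}

#' @export
predict_tags.linear_tagger <- function(model, tokens_list, type = c("tags", "scores")) {
  type <- match.arg(type)
  if (!is.list(tokens_list)) tokens_list <- list(tokens_list)
  feats <- lapply(tokens_list, token_features)
  X <- feature_matrix(feats, model$vocab)
  p <- as.numeric(stats::predict(model$fit, newx = X, s = model$lambda,
                                 type = "response"))
  lens <- lengths(tokens_list)
  stops <- cumsum(lens)
  starts <- stops - lens + 1L
  out <- vector("list", length(tokens_list))
  for (i in seq_along(out)) {
    pi <- if (lens[i]) p[starts[i]:stops[i]] else numeric(0)
    liver <- pi >= 0.5
    tags <- rep("O", lens[i])
    if (any(liver)) {
      run_start <- liver & !c(FALSE, liver[-length(liver)])
      tags[liver] <- "I-LIVER"
      tags[run_start] <- "B-LIVER"
    }
    if (type == "tags") {
      out[[i]] <- tags
    } else {
      m <- matrix(0, nrow = lens[i], ncol = length(IOB_TAGSET),
                  dimnames = list(NULL, IOB_TAGSET))
      m[, 1L] <- 1 - pi
      m[cbind(seq_len(lens[i]), ifelse(tags == "I-LIVER", 3L, 2L))] <- pi
      out[[i]] <- m
    }
  }
  out
}

tags_to_scores <- function(tags) {
  m <- matrix(0, nrow = length(tags), ncol = length(IOB_TAGSET),
              dimnames = list(NULL, IOB_TAGSET))
  m[cbind(seq_along(tags), match(tags, IOB_TAGSET))] <- 1
  m
}

#' Gate sentences with a tagger
#'
#' Tokenizes each sentence, predicts tags and applies [ner_gate()].
#'
#' @param text character vector of sentences.
#' @param tagger a tagger from [train_tagger()].
#' @return logical vector (`TRUE` = liver-related).
#' @export
tagger_gate <- function(text, tagger) {
  toks <- tokenize_words(text)
  tags <- predict_tags(tagger, toks)
  vapply(seq_along(tags), function(i) {
    if (!length(tags[[i]])) FALSE else ner_gate(tags[[i]])
  }, logical(1))
}
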