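#' Assemble a document classification pipeline
#'
#' Four named pipelines mirror the models compared for labeling
#' classification:
#' * `"deep"` — token-tagger (NER) context gate, then a trained sentence
#'   classifier;
#' * `"hybrid"` — string-pattern context gate, then a trained sentence
#'   classifier;
#' * `"keyword"` — no gate, keyword dictionary classifier;
#' * `"ungated"` — no gate, trained sentence classifier applied to every
#'   sentence.
#'
#' @param name pipeline name (fixes the gate type).
#' @param classifier sentence classifier from [train_classifier()];
#'   defaults to the keyword baseline for `"keyword"`, required otherwise.
#' @param tagger tagger from [train_tagger()] (deep pipeline); defaults to
#'   the lexicon tagger.
#' @param context_lexicon lexicon for the string gate (hybrid pipeline).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(name = c("deep", "hybrid", "keyword", "ungated"),
                            classifier = NULL, tagger = NULL,
                            context_lexicon = default_context_lexicon()) {
  name <- match.arg(name)
  gate <- switch(name, deep = "ner", hybrid = "string", keyword = "none",
                 ungated = "none")
  if (name == "keyword") {
    if (is.null(classifier)) classifier <- train_classifier(backend = "keyword")
    if (!inherits(classifier, "keyword_clf")) {
      stopf("the keyword pipeline requires a keyword classifier")
    }
  } else if (is.null(classifier)) {
    stopf("pipeline '%s' requires a trained sentence classifier", name)
  }
  if (gate == "ner" && is.null(tagger)) tagger <- train_tagger(backend = "lexicon")
  structure(list(name = name, gate = gate, classifier = classifier,
                 tagger = tagger, context_lexicon = context_lexicon),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("<pipeline_config> %s (gate: %s, classifier: %s)\n",
              x$name, x$gate, x$classifier$backend))
  invisible(x)
}

#' Any-positive aggregation of sentence labels
#'
#' A document is DILI-positive iff any of its sentences is DILI-positive
#' (logical OR); an empty label set aggregates to 0.
#'
#' @param labels vector of 0/1 sentence labels.
#' @return 0 or 1.
#' @export
aggregate_labels <- function(labels) {
  if (!length(labels)) return(0L)
  stopifnot(all(labels %in% c(0L, 1L)))
  as.integer(any(labels == 1L))
}

# gate + classify the sentences of one document; shared by the pipelines
classify_sentences <- function(text, config) {
  n <- length(text)
  gate_passed <- switch(config$gate,
    none = rep(TRUE, n),
    string = string_gate(text, config$context_lexicon),
    ner = tagger_gate(text, config$tagger)
  )
  label <- integer(n)
  score <- numeric(n)
  if (any(gate_passed)) {
    pred <- predict(config$classifier, text[gate_passed])
    label[gate_passed] <- pred$label
    score[gate_passed] <- pred$score
  }
  data.frame(index = seq_len(n), text = text, gate_passed = gate_passed,
             label = label, score = score, stringsAsFactors = FALSE)
}

#' Classify one labeling document
#'
#' Splits the document into sentences, gates each sentence for liver
#' context, classifies the gated sentences, and aggregates with the
#' any-positive rule. Gated-out sentences are recorded with label 0, so
#' every positive document carries the sentences that triggered it.
#'
#' @param doc a one-row document data frame (columns `doc_id`, `text`), or
#'   a character scalar of section text.
#' @param config a [pipeline_config()].
#' @return a list of class `doc_prediction`: `doc_id`, `label`,
#'   `sentences` (per-sentence predictions) and `trigger_sentences` (the
#'   positive ones).
#' @export
classify_document <- function(doc, config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(doc)) doc <- data.frame(doc_id = "doc", text = doc,
                                           stringsAsFactors = FALSE)
  stopifnot(nrow(doc) == 1L)
  sents <- split_sentences(doc$text)
  if (!length(sents)) {
    warnf("document %s has no sentences after splitting; labeled 0", doc$doc_id)
    empty <- data.frame(index = integer(0), text = character(0),
                        gate_passed = logical(0), label = integer(0),
                        score = numeric(0), stringsAsFactors = FALSE)
    return(structure(list(doc_id = doc$doc_id, label = 0L, sentences = empty,
                          trigger_sentences = empty),
                     class = "doc_prediction"))
  }
  preds <- classify_sentences(sents, config)
  structure(list(doc_id = doc$doc_id,
                 label = aggregate_labels(preds$label),
                 sentences = preds,
                 trigger_sentences = preds[preds$label == 1L, , drop = FALSE]),
            class = "doc_prediction")
}

#' @export
print.doc_prediction <- function(x, ...) {
  cat(sprintf("<doc_prediction> %s: label %d (%d trigger sentence%s)\n",
              x$doc_id, x$label, nrow(x$trigger_sentences),
              if (nrow(x$trigger_sentences) == 1L) "" else "s"))
  invisible(x)
}

#' Classify a document corpus
#'
#' Order-preserving map of [classify_document()] over the corpus.
#'
#' @param docs document data frame.
#' @param config a [pipeline_config()].
#' @return a list of class `corpus_prediction` with `predictions` (data
#'   frame of `doc_id`, `label`, `n_triggers`), `details` (per-document
#'   [classify_document()] results) and `summary` counts.
#' @export
classify_corpus <- function(docs, config) {
  details <- lapply(seq_len(nrow(docs)), function(i) {
    tryCatch(classify_document(docs[i, , drop = FALSE], config),
             error = function(e) stopf("document %s: %s", docs$doc_id[i],
                                       conditionMessage(e)))
  })
  predictions <- data.frame(
    doc_id = docs$doc_id,
    label = vapply(details, `[[`, integer(1), "label"),
    n_triggers = vapply(details, function(d) nrow(d$trigger_sentences), integer(1)),
    stringsAsFactors = FALSE
  )
  structure(list(predictions = predictions, details = details,
                 summary = list(n_docs = nrow(docs),
                                n_positive = sum(predictions$label == 1L),
                                n_negative = sum(predictions$label == 0L))),
            class = "corpus_prediction")
}

#' @export
print.corpus_prediction <- function(x, ...) {
  cat(sprintf("<corpus_prediction> %d documents: %d positive, %d negative\n",
              x$summary$n_docs, x$summary$n_positive, x$summary$n_negative))
  invisible(x)
}

#' Write corpus predictions as JSON lines
#'
#' One record per document with the predicted label and the trigger
#' sentence indices and scores (per-sentence provenance).
#'
#' @param pred a `corpus_prediction` from [classify_corpus()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(pred, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (d in pred$details) {
    rec <- list(doc_id = d$doc_id, label = d$label,
                trigger_indices = d$trigger_sentences$index,
                trigger_scores = round(d$trigger_sentences$score, 6))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con,
               useBytes = TRUE)
  }
  invisible(path)
}
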