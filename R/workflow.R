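RUN_CONFIG_KEYS <- list(
  top = c("run_name", "seed", "synth", "pipeline", "evaluation"),
  synth = c("n_docs", "sentences_min", "sentences_max",
            "doc_positive_prevalence", "liver_negative_frame_rate",
            "dup_rate", "n_positive_docs", "unseen_variants"),
  pipeline = c("name", "classifier_backend", "tagger_backend"),
  evaluation = c("test_fraction", "cv_reps", "cv_folds", "permutation_reps")
)

#' Default demonstration run configuration
#'
#' A self-contained configuration: synthetic corpus, hybrid pipeline with
#' the linear sentence backend, document-level evaluation on a held-out
#' split, no cross-validation or permutation repetitions.
#'
#' @param seed integer seed for the whole run.
#' @return a validated run configuration list.
#' @export
demo_config <- function(seed = 1L) {
  validate_run_config(list(
    run_name = "demo",
    seed = as.integer(seed),
    synth = list(n_docs = 150),
    pipeline = list(name = "hybrid", classifier_backend = "linear",
                    tagger_backend = "lexicon"),
    evaluation = list(test_fraction = 0.2, cv_reps = 0, cv_folds = 5,
                      permutation_reps = 0)
  ))
}

#' Read and validate a run configuration
#'
#' YAML file with sections `synth`, `pipeline` and `evaluation`; unknown
#' keys are rejected so typos fail loudly before any work is done.
#'
#' @param path YAML file path.
#' @return validated configuration list.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

validate_run_config <- function(config) {
  if (!is.list(config)) stopf("config must be a mapping")
  check_keys <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra)) stopf("unknown config key%s in %s: %s",
                             if (length(extra) > 1L) "s" else "", where,
                             paste(extra, collapse = ", "))
  }
  check_keys(config, RUN_CONFIG_KEYS$top, "top level")
  config$run_name <- config$run_name %||% "run"
  config$seed <- as.integer(config$seed %||% 1L)
  config$synth <- config$synth %||% list()
  config$pipeline <- config$pipeline %||% list()
  config$evaluation <- config$evaluation %||% list()
  check_keys(config$synth, RUN_CONFIG_KEYS$synth, "synth")
  check_keys(config$pipeline, RUN_CONFIG_KEYS$pipeline, "pipeline")
  check_keys(config$evaluation, RUN_CONFIG_KEYS$evaluation, "evaluation")
  config$pipeline$name <- config$pipeline$name %||% "hybrid"
  if (!config$pipeline$name %in% c("deep", "hybrid", "keyword", "ungated")) {
    stopf("unknown pipeline name: %s", config$pipeline$name)
  }
  config$pipeline$classifier_backend <- config$pipeline$classifier_backend %||% "linear"
  config$pipeline$tagger_backend <- config$pipeline$tagger_backend %||% "lexicon"
  stopifnot(config$pipeline$classifier_backend %in% c("linear", "keyword"),
            config$pipeline$tagger_backend %in% c("lexicon", "linear"))
  ev <- config$evaluation
  config$evaluation <- list(test_fraction = ev$test_fraction %||% 0.2,
                            cv_reps = as.integer(ev$cv_reps %||% 0L),
                            cv_folds = as.integer(ev$cv_folds %||% 5L),
                            permutation_reps = as.integer(ev$permutation_reps %||% 0L))
  config
}

# training sentences for a pipeline: the gated subset of the training
# ledger (every sentence for the ungated pipeline)
training_sentences <- function(ledger, config, tagger) {
  keep <- switch(config$pipeline$name,
    hybrid = string_gate(ledger$text),
    deep = tagger_gate(ledger$text, tagger),
    rep(TRUE, nrow(ledger))
  )
  ledger[keep, , drop = FALSE]
}

#' Run the full training and evaluation workflow
#'
#' Generates a synthetic labeling corpus, splits documents into stratified
#' train/test partitions, trains the configured pipeline's components on
#' training-document sentences, classifies the test documents, and writes
#' all artifacts (corpus, split, models' metadata, predictions, metrics,
#' optional cross-validation and permutation reports) into `outdir`.
#' Rerunning with the same configuration and seed reproduces the artifacts
#' byte for byte.
#'
#' @param config configuration list from [read_run_config()] or
#'   [demo_config()].
#' @param outdir output directory (created if missing).
#' @return (invisibly) a list with the fitted `pipeline`, the document
#'   `metrics_report`, and paths to the written artifacts.
#' @export
run_workflow <- function(config, outdir) {
  config <- validate_run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  sp <- do.call(synth_params, c(config$synth, list(seed = seed)))
  corpus <- generate_corpus(sp)
  docs <- corpus$documents
  ledger <- corpus$ledger

  split <- stratified_split(docs, "dili_label",
                            config$evaluation$test_fraction, seed = seed)
  train_ledger <- ledger[ledger$doc_id %in% split$train$doc_id, , drop = FALSE]

  tagger <- NULL
  if (config$pipeline$name == "deep") {
    if (config$pipeline$tagger_backend == "lexicon") {
      tagger <- train_tagger(backend = "lexicon")
    } else {
      seqs <- ledger_to_conll(train_ledger)
      seq_split <- stratified_split(
        data.frame(i = seq_along(seqs),
                   liver = vapply(seqs, function(s) any(s$tags != "O"), logical(1))),
        "liver", 0.2, seed = seed)
      tagger <- train_tagger(seqs[seq_split$train$i], seqs[seq_split$test$i],
                             backend = "linear", seed = seed)
    }
  }

  if (config$pipeline$name == "keyword") {
    classifier <- train_classifier(backend = "keyword")
    train_sents <- train_ledger
  } else {
    train_sents <- training_sentences(train_ledger, config, tagger)
    if (config$pipeline$classifier_backend == "keyword") {
      classifier <- train_classifier(backend = "keyword")
    } else {
      classifier <- train_classifier(train_sents$text, train_sents$dili_label,
                                     backend = "linear", seed = seed)
    }
  }
  pipeline <- pipeline_config(config$pipeline$name, classifier = classifier,
                              tagger = tagger)

  pred <- classify_corpus(split$test, pipeline)
  cm <- confusion(pred$predictions$label, split$test$dili_label)
  rep <- metrics(cm)

  # ---- artifacts ------------------------------------------------------------
  paths <- list(
    config = file.path(outdir, "config.yaml"),
    documents = file.path(outdir, "documents.jsonl"),
    split = file.path(outdir, "split.tsv"),
    sentences = file.path(outdir, "sentences.conll"),
    ledger = file.path(outdir, "ledger.csv"),
    predictions = file.path(outdir, "predictions.jsonl"),
    metrics = file.path(outdir, "metrics.csv"),
    metadata = file.path(outdir, "metadata.json")
  )
  yaml::write_yaml(config, paths$config)
  config_hash <- unname(tools::md5sum(paths$config))
  write_documents(docs, paths$documents)
  write_split(split, paths$split)
  write_conll(ledger_to_conll(ledger), paths$sentences)
  led_out <- ledger[, c("doc_id", "index", "frame", "dili_label", "liver_label", "text")]
  utils::write.csv(led_out, paths$ledger, row.names = FALSE)
  write_predictions(pred, paths$predictions)

  metrics_df <- data.frame(
    metric = c("mcc", "precision", "recall", "f1", "fpr", "accuracy",
               "tp", "fp", "fn", "tn"),
    value = c(rep$mcc, rep$precision, rep$recall, rep$f1, rep$fpr, rep$accuracy,
              cm$tp, cm$fp, cm$fn, cm$tn),
    config_hash = config_hash
  )
  utils::write.csv(metrics_df, paths$metrics, row.names = FALSE)

  cv <- NULL
  if (config$evaluation$cv_reps > 0L) {
    cv <- repeated_cv(train_sents$text, train_sents$dili_label,
                      k = config$evaluation$cv_folds,
                      reps = config$evaluation$cv_reps, seed = seed)
    cv_df <- cv$summary
    cv_df$config_hash <- config_hash
    paths$cv <- file.path(outdir, "cv.csv")
    utils::write.csv(cv_df, paths$cv, row.names = FALSE)
  }
  perm <- NULL
  if (config$evaluation$permutation_reps > 1L) {
    perm <- permutation_test(train_sents$text, train_sents$dili_label,
                             reps = config$evaluation$permutation_reps,
                             seed = seed)
    paths$permutation <- file.path(outdir, "permutation.json")
    jsonlite::write_json(list(observed = perm$observed, permuted = perm$permuted,
                              t_statistic = perm$t_statistic,
                              p_value = perm$p_value,
                              config_hash = config_hash),
                         paths$permutation, auto_unbox = TRUE, digits = NA)
  }

  jsonlite::write_json(list(run_name = config$run_name, seed = seed,
                            config_hash = config_hash,
                            package_version = as.character(utils::packageVersion("dilitext")),
                            n_docs = nrow(docs), n_train = nrow(split$train),
                            n_test = nrow(split$test),
                            n_train_sentences = nrow(train_sents),
                            artifacts = lapply(paths, basename)),
                       paths$metadata, auto_unbox = TRUE, digits = NA)

  invisible(list(pipeline = pipeline, metrics = rep, confusion = cm,
                 cv = cv, permutation = perm, config_hash = config_hash,
                 paths = paths))
}
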