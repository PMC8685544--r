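#' Binary confusion matrix
#'
#' @param pred,truth 0/1 vectors of equal, positive length (positive class
#'   = 1).
#' @return an object of class `confusion_matrix` with fields `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
confusion <- function(pred, truth) {
  if (length(pred) != length(truth)) stopf("pred and truth lengths differ")
  if (!length(pred)) stopf("empty prediction vector")
  stopifnot(all(pred %in% c(0, 1)), all(truth %in% c(0, 1)))
  confusion_matrix(tp = sum(pred == 1 & truth == 1),
                   fp = sum(pred == 1 & truth == 0),
                   fn = sum(pred == 0 & truth == 1),
                   tn = sum(pred == 0 & truth == 0))
}

#' @rdname confusion
#' @param tp,fp,fn,tn non-negative counts.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stopifnot(all(counts >= 0), all(counts == floor(counts)))
  structure(as.list(as.integer(counts)) |> stats::setNames(names(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> tp=%d fp=%d fn=%d tn=%d\n", x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Computes the Matthews correlation coefficient
#' \deqn{MCC = (tp \cdot tn - fp \cdot fn) / \sqrt{(tp+fp)(tp+fn)(tn+fp)(tn+fn)}}
#' together with precision, recall, F1, false-positive rate and accuracy.
#' Any metric whose denominator is zero (including MCC with a zero
#' marginal) is reported as 0 by convention and flagged in
#' `zero_denominator`. Values are stored at full precision; round with
#' [round_half_up()] for presentation.
#'
#' @param cm a `confusion_matrix` (or anything [confusion()] returns).
#' @return a list of class `metrics_report`: `mcc`, `precision`, `recall`,
#'   `f1`, `fpr`, `accuracy`, `zero_denominator` (character vector of
#'   flagged metrics).
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  n <- tp + fp + fn + tn
  if (n == 0L) stopf("all-zero confusion matrix")
  flagged <- character(0)
  div <- function(num, den, what) {
    if (den == 0) {
      flagged <<- c(flagged, what)
      return(0)
    }
    num / den
  }
  precision <- div(tp, tp + fp, "precision")
  recall <- div(tp, tp + fn, "recall")
  f1 <- div(2 * precision * recall, precision + recall, "f1")
  fpr <- div(fp, fp + tn, "fpr")
  accuracy <- (tp + tn) / n
  denom <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) {
    flagged <- c(flagged, "mcc")
    0
  } else {
    (tp * tn - fp * fn) / denom
  }
  structure(list(mcc = mcc, precision = precision, recall = recall, f1 = f1,
                 fpr = fpr, accuracy = accuracy, zero_denominator = flagged),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 2, ...) {
  vals <- unlist(x[c("mcc", "precision", "recall", "f1", "fpr", "accuracy")])
  cat("<metrics_report>\n")
  for (nm in names(vals)) cat(sprintf("  %-9s %.*f\n", nm, digits, round_half_up(vals[[nm]], digits)))
  if (length(x$zero_denominator)) {
    cat("  zero-denominator metrics reported as 0:",
        paste(x$zero_denominator, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Token-level tagging metrics
#'
#' Micro-averaged precision, recall and F1 over tokens with positive class
#' `{B-LIVER, I-LIVER}` (a predicted liver token counts as correct iff the
#' true tag is also a liver tag).
#'
#' @param pred_tags,true_tags lists of tag vectors, aligned sequence by
#'   sequence and token by token.
#' @return a `metrics_report` (see [metrics()]).
#' @export
token_metrics <- function(pred_tags, true_tags) {
  if (length(pred_tags) != length(true_tags)) stopf("sequence counts differ")
  bad <- which(lengths(pred_tags) != lengths(true_tags))
  if (length(bad)) stopf("misaligned sequence lengths at index %d", bad[1])
  p <- unlist(pred_tags) %in% LIVER_TAGS
  t <- unlist(true_tags) %in% LIVER_TAGS
  metrics(confusion(as.integer(p), as.integer(t)))
}

# stratified fold assignment: within each class, the first (n_c mod k)
# shuffled folds get one extra item
stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) stopf("class %s has fewer than k=%d members", cl, k)
    idx <- idx[sample.int(length(idx))]
    base <- length(idx) %/% k
    extra <- length(idx) %% k
    sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
    folds[idx] <- rep(seq_len(k), times = sizes)
  }
  folds
}

#' Repeated stratified k-fold cross-validation
#'
#' For each repetition the data are reshuffled into k label-stratified
#' folds; the trainer is fitted on k-1 folds and evaluated on the held-out
#' fold. Summaries are mean and standard deviation over all reps x k fold
#' results. Seed-reproducible.
#'
#' @param text sentence texts.
#' @param labels 0/1 DILI labels.
#' @param trainer `function(text, labels)` returning a classifier whose
#'   `predict()` yields a `label` column; defaults to the linear backend.
#' @param k number of folds (default 5).
#' @param reps number of repetitions (default 100).
#' @param seed integer seed.
#' @return a list of class `cv_summary`: `k`, `reps`, `folds` (per-fold
#'   metric data frame) and `summary` (mean and sd per metric).
#' @export
repeated_cv <- function(text, labels, trainer = NULL, k = 5L, reps = 100L,
                        seed = 1L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stopf("both classes must be present")
  if (length(labels) < k) stopf("need at least k observations")
  if (is.null(trainer)) {
    trainer <- function(tx, y) train_classifier(tx, y, backend = "linear", seed = seed)
  }
  rows <- with_seed(as.integer(seed), {
    out <- vector("list", reps * k)
    for (r in seq_len(reps)) {
      folds <- stratified_folds(labels, k)
      for (f in seq_len(k)) {
        te <- folds == f
        model <- trainer(text[!te], labels[!te])
        pred <- predict(model, text[te])$label
        m <- metrics(confusion(pred, labels[te]))
        out[[(r - 1L) * k + f]] <- data.frame(
          rep = r, fold = f, n_test = sum(te), accuracy = m$accuracy,
          recall = m$recall, precision = m$precision, f1 = m$f1, mcc = m$mcc)
      }
    }
    out
  })
  folds_df <- do.call(rbind, rows)
  metric_cols <- c("accuracy", "recall", "precision", "f1", "mcc")
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(cn) mean(folds_df[[cn]]), numeric(1)),
    sd = vapply(metric_cols, function(cn) stats::sd(folds_df[[cn]]), numeric(1)),
    row.names = NULL
  )
  structure(list(k = k, reps = reps, folds = folds_df, summary = summary),
            class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  cat(sprintf("<cv_summary> %d x %d-fold cross-validation\n", x$reps, x$k))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-9s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Permutation (label-shuffling) significance test
#'
#' Establishes the chance-level accuracy distribution: in each repetition
#' the data are resampled into a stratified train/test split and the
#' trainer is fitted twice — once on the original labels (observed) and
#' once after randomly shuffling all labels before the resample (permuted).
#' The two accuracy samples are compared with a two-sided Welch t-test.
#'
#' @inheritParams repeated_cv
#' @param reps number of resampling repetitions (at least 2).
#' @param test_fraction held-out fraction per resample.
#' @return a list of class `permutation_report`: `observed` and `permuted`
#'   accuracy vectors, `t_statistic`, `p_value`.
#' @export
permutation_test <- function(text, labels, trainer = NULL, reps = 100L,
                             test_fraction = 0.2, seed = 1L) {
  labels <- as.integer(labels)
  if (reps < 2L) stopf("reps must be at least 2")
  if (length(unique(labels)) < 2L) stopf("both classes must be present")
  if (is.null(trainer)) {
    trainer <- function(tx, y) train_classifier(tx, y, backend = "linear", seed = seed)
  }
  run_once <- function(y) {
    # stratified test draw on the (possibly shuffled) labels
    te <- logical(length(y))
    for (cl in unique(y)) {
      ic <- which(y == cl)
      n_te <- max(1L, round(length(ic) * test_fraction))
      te[sample(ic, n_te)] <- TRUE
    }
    tr <- which(!te)
    if (length(unique(y[tr])) < 2L) return(NA_real_)
    model <- trainer(text[tr], y[tr])
    mean(predict(model, text[te])$label == y[te])
  }
  res <- with_seed(as.integer(seed), {
    observed <- numeric(reps)
    permuted <- numeric(reps)
    for (r in seq_len(reps)) {
      observed[r] <- run_once(labels)
      permuted[r] <- run_once(sample(labels))
    }
    list(observed = observed, permuted = permuted)
  })
  tt <- stats::t.test(res$observed, res$permuted, alternative = "two.sided",
                      var.equal = FALSE)
  structure(list(observed = res$observed, permuted = res$permuted,
                 t_statistic = unname(tt$statistic), p_value = tt$p.value),
            class = "permutation_report")
}

#' @export
print.permutation_report <- function(x, ...) {
  cat(sprintf("<permutation_report> observed %.3f +/- %.3f vs permuted %.3f +/- %.3f (t=%.2f, p=%.3g)\n",
              mean(x$observed), stats::sd(x$observed), mean(x$permuted),
              stats::sd(x$permuted), x$t_statistic, x$p_value))
  invisible(x)
}
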