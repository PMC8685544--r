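test_that("confusion counts match a brute-force tally", {
  expect_identical(confusion(c(1, 0), c(1, 0))[c("tp", "tn", "fp", "fn")],
                   list(tp = 1L, tn = 1L, fp = 0L, fn = 0L))
  expect_identical(confusion(1, 0)$fp, 1L)
  expect_error(confusion(c(1, 0), 1), "lengths differ")
  expect_error(confusion(integer(0), integer(0)), "empty")
  set.seed(17)
  for (i in 1:10) {
    p <- sample(0:1, 200, replace = TRUE)
    t <- sample(0:1, 200, replace = TRUE)
    cm <- confusion(p, t)
    tp <- fp <- fn <- tn <- 0L
    for (j in 1:200) {
      if (p[j] == 1 && t[j] == 1) tp <- tp + 1L
      if (p[j] == 1 && t[j] == 0) fp <- fp + 1L
      if (p[j] == 0 && t[j] == 1) fn <- fn + 1L
      if (p[j] == 0 && t[j] == 0) tn <- tn + 1L
    }
    expect_identical(c(cm$tp, cm$fp, cm$fn, cm$tn), c(tp, fp, fn, tn))
    expect_identical(cm$tp + cm$fp + cm$fn + cm$tn, 200L)
  }
})

test_that("the published confusion counts reproduce the printed metrics", {
  r2 <- function(x) round_half_up(x, 2)
  deep <- metrics(confusion_matrix(tp = 40, fp = 11, fn = 0, tn = 99))
  expect_identical(r2(c(deep$mcc, deep$precision, deep$recall)), c(0.84, 0.78, 1.00))
  hybrid <- metrics(confusion_matrix(tp = 40, fp = 9, fn = 0, tn = 101))
  expect_identical(r2(c(hybrid$mcc, hybrid$precision, hybrid$recall)), c(0.87, 0.82, 1.00))
  keyword <- metrics(confusion_matrix(tp = 36, fp = 26, fn = 4, tn = 84))
  expect_identical(r2(c(keyword$mcc, keyword$precision, keyword$recall)), c(0.60, 0.58, 0.90))
  perfect <- metrics(confusion_matrix(tp = 10, fp = 0, fn = 0, tn = 10))
  expect_equal(c(perfect$mcc, perfect$recall, perfect$fpr), c(1, 1, 0))
})

test_that("MCC has its swap symmetry and relabeling antisymmetry", {
  set.seed(23)
  for (i in 1:50) {
    cm <- confusion_matrix(tp = sample(0:40, 1), fp = sample(0:40, 1),
                           fn = sample(0:40, 1), tn = sample(1:40, 1))
    swapped <- confusion_matrix(tp = cm$tn, fp = cm$fn, fn = cm$fp, tn = cm$tp)
    flipped <- confusion_matrix(tp = cm$fp, fp = cm$tp, fn = cm$tn, tn = cm$fn)
    expect_equal(metrics(swapped)$mcc, metrics(cm)$mcc)
    expect_equal(metrics(flipped)$mcc, -metrics(cm)$mcc)
  }
})

test_that("metrics agree with closed-form formulas from the raw vectors", {
  set.seed(29)
  for (i in 1:20) {
    p <- sample(0:1, 150, replace = TRUE)
    t <- sample(0:1, 150, replace = TRUE)
    m <- metrics(confusion(p, t))
    tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t); tn <- sum(!p & !t)
    expect_equal(m$precision, tp / (tp + fp))
    expect_equal(m$recall, tp / (tp + fn))
    expect_equal(m$fpr, fp / (fp + tn))
    expect_equal(m$accuracy, mean(p == t))
    expect_equal(m$mcc, (tp * tn - fp * fn) /
                   sqrt(tp + fp) / sqrt(tp + fn) / sqrt(tn + fp) / sqrt(tn + fn))
    expect_equal(m$f1, 2 * tp / (2 * tp + fp + fn))
  }
})

test_that("zero-denominator metrics are flagged and reported as 0", {
  m <- metrics(confusion_matrix(tp = 0, fp = 0, fn = 5, tn = 5))
  expect_identical(m$precision, 0)
  expect_identical(m$mcc, 0)
  expect_true(all(c("precision", "mcc") %in% m$zero_denominator))
  expect_error(metrics(confusion_matrix(0, 0, 0, 0)), "all-zero")
})

test_that("token metrics micro-average over the liver tag class", {
  led <- fx_corpus()$ledger
  truth <- led$tags[1:50]
  expect_identical(token_metrics(truth, truth)$f1, 1)
  all_o <- lapply(truth, function(t) rep("O", length(t)))
  expect_identical(token_metrics(all_o, truth)$recall, 0)
  expect_error(token_metrics(truth[1:2], truth[1:3]), "sequence counts")
  expect_error(token_metrics(list(c("O", "O")), list("O")), "misaligned")
  set.seed(31)
  pred <- lapply(truth, function(t) sample(c("O", "B-LIVER", "I-LIVER"),
                                           length(t), replace = TRUE))
  m <- token_metrics(pred, truth)
  p <- unlist(pred) != "O"
  t <- unlist(truth) != "O"
  expect_equal(m$precision, sum(p & t) / sum(p))
  expect_equal(m$recall, sum(p & t) / sum(t))
})

test_that("stratified folds partition every repetition with balanced sizes", {
  # class sizes as in a 540:1313 liver-related sentence set
  labels <- rep(c(1L, 0L), c(540L, 1313L))
  set.seed(37)
  folds <- dilitext:::stratified_folds(labels, 5L)
  expect_identical(sort(as.integer(table(folds)), decreasing = TRUE),
                   c(371L, 371L, 371L, 370L, 370L))
  # each item lands in exactly one fold; per-fold class counts within 1 of n_c/k
  expect_identical(length(folds), length(labels))
  for (f in 1:5) {
    expect_lte(abs(sum(labels[folds == f] == 1L) - 108), 1)
  }
})

test_that("repeated CV is seed-reproducible and near-perfect on separable data", {
  g <- fx_gated()
  a <- repeated_cv(g$text, g$dili_label, k = 5, reps = 2, seed = 41)
  b <- repeated_cv(g$text, g$dili_label, k = 5, reps = 2, seed = 41)
  expect_identical(a$summary, b$summary)
  expect_identical(nrow(a$folds), 10L)
  expect_gte(a$summary$mean[a$summary$metric == "accuracy"], 0.99)
  expect_error(repeated_cv(g$text, rep(1L, nrow(g))), "both classes")
  few <- g[c(which(g$dili_label == 1)[1:3], which(g$dili_label == 0)[1:20]), ]
  expect_error(repeated_cv(few$text, few$dili_label, k = 5, reps = 1), "fewer than k")
})

test_that("the permutation test separates signal from chance and is reproducible", {
  g <- fx_gated()
  a <- permutation_test(g$text, g$dili_label, reps = 12, seed = 43)
  b <- permutation_test(g$text, g$dili_label, reps = 12, seed = 43)
  expect_identical(a$observed, b$observed)
  expect_identical(a$p_value, b$p_value)
  expect_lt(a$p_value, 0.01)
  majority <- max(mean(g$dili_label), 1 - mean(g$dili_label))
  expect_lte(abs(mean(a$permuted) - majority), 3 * sd(a$permuted))
  expect_gt(mean(a$observed), mean(a$permuted))
  expect_error(permutation_test(g$text, g$dili_label, reps = 1), "at least 2")
})

test_that("pure-noise features show no observed/permuted separation", {
  set.seed(47)
  nonsig <- 0L
  for (meta in 1:10) {
    text <- vapply(1:120, function(i) paste(sample(letters, 8, replace = TRUE),
                                            collapse = " "), character(1))
    labels <- rep(c(0L, 1L), 60)
    p <- permutation_test(text, labels, reps = 8, seed = meta)$p_value
    if (p >= 0.01) nonsig <- nonsig + 1L
  }
  expect_gte(nonsig, 8L)
})
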