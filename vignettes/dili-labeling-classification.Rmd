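---
title: "Hierarchical DILI-risk classification of drug labeling text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical DILI-risk classification of drug labeling text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dilitext)
```

## The problem and the model

The "Warnings and Precautions" section of a prescription drug label mixes
several kinds of statements that all mention the liver: attributable
adverse-reaction reports ("Hepatic toxicity including hepatic failure ...
have been reported"), contraindications ("should not be used by patients
with severe hepatic impairment"), indications ("for the treatment of
chronic hepatitis B") and laboratory-monitoring instructions ("monitor
serum ALT periodically"). Only the first kind signals drug-induced liver
injury (DILI) risk, so dictionary matching on hepatic terms systematically
over-calls: the decisive information is not whether a hepatic term occurs
but in what frame it occurs.

`dilitext` therefore classifies documents hierarchically:

1. **Sentence splitting** — a document is broken into ordered sentences
   $s_1, s_2, \dots, s_i$ by a deterministic rule-based splitter.
2. **Context gating** — each sentence is tested for liver context, either
   by broad string patterns (the *hybrid* pipeline) or by a token-level
   tagger over the IOB tagset $\{O, B\text{-LIVER}, I\text{-LIVER}\}$ (the
   *deep* pipeline). With per-token scores $t_{ij}$, a sentence passes the
   gate iff $\exists j: \arg\max(t_{ij}) \in \{B\text{-LIVER},
   I\text{-LIVER}\}$; argmax ties resolve to $O$, so a tie never opens the
   gate.
3. **Sentence classification** — gated sentences receive a binary DILI
   label from a classifier trained on liver-related sentences only, which
   converts an extremely imbalanced corpus-wide problem (on the order of
   2% positives) into a roughly 1:2 on-topic problem.
4. **Any-positive aggregation** — the document label is
   $\bigvee_i \hat{y}(s_i)$: positive iff at least one sentence is
   positive, with the triggering sentences retained for human review.
   Gated-out sentences are recorded with label 0.

A *keyword* pipeline (no gate, dictionary classifier) and an *ungated*
pipeline (trained classifier on every sentence) are included as named
configurations for comparison.

## Backends and tunable parameters

Two interchangeable backends implement each learnable stage.

* **Lexicon tagger** (`train_tagger(backend = "lexicon")`): tags token
  spans that match the shipped liver-term pattern file. It is
  deterministic and requires no training; on the synthetic corpus it is an
  exact oracle because the generator draws its terms from the same file.
* **Linear tagger** (`backend = "linear"`): ridge-logistic token
  classification (glmnet) over lower-cased token identity, padded
  character 3-grams, compressed word shape, and neighbor
  identities/shapes. Liver tokens are rare (1–2%), so observations are
  class-balance weighted; without this the penalized fit collapses to the
  all-$O$ solution. The regularization strength is selected from the grid
  `c(0.1, 0.03, 0.01, 0.003)` by token-level F1 on a development split —
  the analogue of best-epoch checkpointing. Character n-grams and
  neighbor features are what let this backend recognize term variants
  (ASAT, ALAT, transaminitis) that a fixed pattern list misses.
* **Linear sentence classifier** (`train_classifier(backend = "linear")`):
  uncased bag of 1–2 grams with ridge-logistic regression, fixed
  `lambda = 0.01`. The decision threshold is fixed at 0.5 and never
  tuned. Bigrams are essential: they separate "hepatitis" in "chronic
  hepatitis B" from "hepatitis" as a reported reaction.
* **Keyword classifier** (`backend = "keyword"`): any-match against the
  editable DILI keyword file; its insensitivity to context is the failure
  mode the gated pipelines remove.

Transformer-based token and sequence classifiers fit the same contracts
(`predict_tags()` score matrices; `predict()` label/score frames) but are
not shipped; the linear backends are the desk-scale reference
implementation.

Matching modes: lexicon patterns match either as case-insensitive
substrings/stems ("hepat" covers hepatic, hepatitis, hepatotoxicity) or as
whole words, the right mode for short enzyme abbreviations (ALT, AST)
that would otherwise fire inside common words. Both modes can be mixed in
one file.

## The synthetic corpus generator

Because real labeled corpora of this kind cannot be redistributed, the
package ships a template-grammar generator (`generate_corpus()`) that
emulates labeling-style sentences in five frames: attributable hepatic ADR,
hepatic contraindication, hepatic indication, laboratory monitoring, and
non-liver content. It returns full ground truth at every level — token
IOB tags, sentence DILI and liver-context labels, and document labels
(the OR of sentence labels) — so every pipeline stage is testable without
external data.

Default conditions and why:

* `doc_positive_prevalence = 0.27` — matches a 40/150 positive share of
  evaluation documents, the regime the document metrics are reported in.
* sentences per document uniform on 15–45 (mean 30) and one to three ADR
  sentences per positive document (mean 2) — together these put the
  sentence-level positive fraction near 0.018, reproducing the
  order-of-2% imbalance (540 of 29,252) that motivates context gating.
* `liver_negative_frame_rate = 0.7` — seventy percent of liver-mention
  sentences are DILI-negative frames, mirroring the roughly 540:1,313
  positive:negative ratio among liver-related sentences.
* `dup_rate = 0.05` — labeling boilerplate recurs across documents; the
  duplication pass only copies DILI-negative sentences over DILI-negative
  slots so document labels are never disturbed.
* `unseen_variants` — off by default; when on, hepatic terms and enzyme
  abbreviations absent from every shipped lexicon are injected, which is
  how the fixed-dictionary failure mode and the learnable tagger's
  advantage on variants are reproduced.

Non-liver adverse-reaction sentences deliberately reuse the same
reporting-cue phrasing ("... has been reported ...") as hepatic ADR
sentences, so cues are class-neutral corpus-wide and the hepatic term
itself carries the document-level signal — as in real labeling
boilerplate.

What the generator does *not* emulate: paraphrase diversity beyond
templates, discourse structure, negation, cross-sentence references, and
the long tail of real clinical language. Passing tests on this corpus
demonstrate that the pipeline mechanics (gating, classification,
aggregation, evaluation) are correct in a regime where the ground truth is
known exactly; they are not evidence about performance on real labeling
text.

An "oracle" configuration exists by construction: the lexicon tagger gates
exactly the liver-mention sentences, and a small dictionary of
reporting-cue phrases (`default_adr_cue_lexicon()`) identifies the
attributable-ADR frame among them. This solvable-by-construction pipeline
recovers every synthetic document label and anchors the end-to-end tests.

## Evaluation machinery

* `metrics()` computes MCC
  $\frac{tp \cdot tn - fp \cdot fn}{\sqrt{(tp+fp)(tp+fn)(tn+fp)(tn+fn)}}$,
  precision, recall, F1, false-positive rate and accuracy from a confusion
  matrix. Any metric with a zero denominator (including MCC with a zero
  marginal) is reported as 0 and flagged — a convention, stated rather
  than silent. Stored values are full precision; presentation rounding is
  half-up to two decimals (`round_half_up()`), matching how such tables
  are conventionally printed.
* `token_metrics()` micro-averages precision/recall/F1 over tokens with
  positive class $\{B\text{-LIVER}, I\text{-LIVER}\}$.
* `stratified_split()` rounds the per-stratum test count half-to-even,
  which makes published splits like 431/109 of 540 (not an exact 80/20)
  representable as per-class rounding outcomes.
* `repeated_cv()` reshuffles into label-stratified k folds per
  repetition. Stratification is a design choice: with a 1:2.4 class
  ratio, unstratified folds destabilize per-fold metrics.
* `permutation_test()` shuffles all labels before each stratified
  train/test resample and compares observed vs permuted accuracies with a
  two-sided Welch t-test (unequal variances — the observed arm typically
  has far smaller spread). Shuffling the full label vector makes the null
  accuracy concentrate at the majority-class prior, which is the
  calibration property the tests assert.
* `oversample()` draws n rows with replacement with probability inversely
  proportional to class frequency (expected 1:1 balance), the standard
  class-weight resampling remedy for imbalanced training.
* `token_attribution()` is leave-one-token-out occlusion with an
  out-of-vocabulary mask token: exact Shapley values are out of scope, but
  for a linear bag-of-ngrams model the link-scale occlusion equals the
  summed coefficients of the n-grams the token participates in, which the
  tests verify to 1e-6.

## Numerical and degenerate-input choices

* Sentence splitting is total and deterministic: any non-empty text yields
  a sentence list; empty text yields none. A document with no sentences
  is classified 0 with a warning rather than an error.
* Dangling `I-LIVER` tags on CoNLL read are repaired to `B-LIVER` with a
  warning; the repair is idempotent. Tags outside the tagset are errors
  naming the line.
* Per-sentence classifier failures inside a document degrade to label 0
  with a logged warning; a recall-oriented reviewer workflow prefers an
  explicit log line over a crashed batch.
* All randomness flows from a single integer seed per entry point; the
  same configuration and seed reproduce corpora and run artifacts byte for
  byte.

## Problem sizes used by the shipped checks

The test suite exercises desk-scale sizes chosen to keep the full run
comfortably reproducible on one CPU: a 60-document fixture corpus for unit
properties; about 5,000 sentences (170 documents) for linear-tagger
training; 1,000 documents for end-to-end label recovery; 2,000
liver-related sentences with 100 label-shuffled resamples for the
permutation-null calibration; and 50 generator seeds for the
keyword-vs-gated precision comparison. The acceptance script runs a
500-document corpus with 5x5-fold cross-validation and 30 permutation
resamples.

## Known limitations

* The template grammar is finite; classifiers can reach perfect scores in
  the default (solvable) regime. That is intended — the corpus tests
  mechanics, not generalization.
* The linear backends are bags of n-grams: they cannot use word order
  beyond bigrams or long-range context, and their scores are not
  calibrated probabilities.
* The keyword and context lexicons are deliberately editable text files;
  labeling vocabulary drifts (dozens of observed variants per preferred
  term), and no fixed list stays complete.
* Sentence-level errors, not document structure, drive the document
  label; documents are never encoded whole, and very long sentences are
  the classifier's to handle (the linear backends have no input-length
  limit; a transformer backend would truncate with a warning).
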