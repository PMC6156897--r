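#' D-score: logit distance to the decision boundary
#'
#' Converts a positive-class probability into its distance from the softmax
#' decision boundary, `ln(p / (1 - p))`. The score is 0 exactly at p = 0.5,
#' strictly increasing in p, and antisymmetric: `d_score(p) = -d_score(1-p)`.
#' Probabilities are clipped to `[eps, 1 - eps]` first so the score is always
#' finite.
#'
#' @param p_positive Numeric vector of probabilities in `[0, 1]`.
#' @param eps Clip width (default 1e-7).
#' @return Numeric vector of D-scores.
#' @export
#' @examples
#' d_score(c(0.5, exp(1) / (1 + exp(1))))
d_score <- function(p_positive, eps = 1e-7) {
  if (any(!is.finite(p_positive))) abort("probabilities must be finite")
  if (any(p_positive < 0 | p_positive > 1)) abort("probabilities must lie in [0, 1]")
  p <- pmin(pmax(p_positive, eps), 1 - eps)
  log(p / (1 - p))
}

#' Rank candidate interactions by D-score
#'
#' Sorts a classification-matrix tibble of candidate drug-gene pairs by
#' decreasing D-score. Ties are broken by (drug_id, gene_id) lexicographic
#' order so the ranking is deterministic across runs.
#'
#' @param cm Tibble with columns `drug_id`, `gene_id`, `p_positive` (e.g.
#'   from [predict_pairs()]).
#' @param eps Probability clip passed to [d_score()].
#' @return Tibble with `rank`, `drug_id`, `gene_id`, `p_positive`, `d_score`,
#'   sorted by `d_score` descending.
#' @export
rank_predictions <- function(cm, eps = 1e-7) {
  stopifnot(all(c("drug_id", "gene_id", "p_positive") %in% names(cm)))
  out <- tibble(
    drug_id = cm$drug_id, gene_id = cm$gene_id,
    p_positive = cm$p_positive,
    d_score = d_score(cm$p_positive, eps)
  )
  ord <- order(-out$d_score, out$drug_id, out$gene_id, method = "radix")
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  out[c("rank", "drug_id", "gene_id", "p_positive", "d_score")]
}

#' Per-sample predictive error between two classifiers
#'
#' For each sample the predictive error is the probability a comparator model
#' assigns to the sample's true class minus the probability the reference
#' network assigns to it. Negative values mean the comparator puts less
#' probability on the truth than the network does, i.e. the network wins on
#' that sample.
#'
#' @param cm_other,cm_ref Aligned class-probability tables (columns
#'   `p_negative`, `p_positive`, or 2-column matrices) for the comparator and
#'   the reference model.
#' @param labels Integer true labels in `{0, 1}`.
#' @return Numeric vector of per-sample errors.
#' @export
predictive_error <- function(cm_other, cm_ref, labels) {
  a <- as_cm_matrix(cm_other)
  b <- as_cm_matrix(cm_ref)
  if (nrow(a) != nrow(b) || nrow(a) != length(labels)) {
    abort("classification matrices and labels are not aligned")
  }
  if (!all(labels %in% c(0, 1))) abort("labels must be 0 or 1")
  col <- labels + 1L  # column 1 = negative class, column 2 = positive class
  a[cbind(seq_len(nrow(a)), col)] - b[cbind(seq_len(nrow(b)), col)]
}

as_cm_matrix <- function(cm) {
  if (is.data.frame(cm)) {
    stopifnot(all(c("p_negative", "p_positive") %in% names(cm)))
    cbind(cm$p_negative, cm$p_positive)
  } else {
    m <- as.matrix(cm)
    stopifnot(ncol(m) == 2)
    m
  }
}

#' Percentage of positive cases among unlabeled pairs
#'
#' The fraction of unlabeled samples called positive at the given threshold.
#' At fixed accuracy a lower value indicates a more conservative,
#' higher-precision predictor.
#'
#' @param cm Class-probability table for the unlabeled samples.
#' @param threshold Decision threshold on `p_positive` (default 0.5, the
#'   zero point of the D-score).
#' @return Fraction in `[0, 1]`.
#' @export
popc <- function(cm, threshold = 0.5) {
  m <- as_cm_matrix(cm)
  if (nrow(m) == 0) abort("no unlabeled samples")
  mean(m[, 2] > threshold)
}

#' Threshold classification metrics
#'
#' Confusion-matrix metrics of a class-probability table against true labels:
#' validation accuracy and the F-score (harmonic mean of precision and recall
#' on the positive class). When precision or recall has a zero denominator it
#' is reported as 0 and flagged.
#'
#' @param cm Class-probability table.
#' @param labels Integer true labels in `{0, 1}`.
#' @param threshold Decision threshold on `p_positive` (default 0.5).
#' @return One-row tibble: `accuracy`, `f_score`, `precision`, `recall`,
#'   counts `tp`, `fp`, `tn`, `fn`, and `zero_denominator`.
#' @export
classification_metrics <- function(cm, labels, threshold = 0.5) {
  m <- as_cm_matrix(cm)
  if (nrow(m) != length(labels)) abort("labels not aligned with predictions")
  if (!all(labels %in% c(0, 1))) abort("labels must be 0 or 1")
  if (length(unique(labels)) < 2) abort("both classes must be represented")
  pred <- as.integer(m[, 2] > threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  zero_den <- (tp + fp) == 0 || (tp + fn) == 0
  precision <- if ((tp + fp) == 0) 0 else tp / (tp + fp)
  recall <- if ((tp + fn) == 0) 0 else tp / (tp + fn)
  f <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  tibble(
    accuracy = (tp + tn) / length(labels),
    f_score = f, precision = precision, recall = recall,
    tp = tp, fp = fp, tn = tn, fn = fn,
    zero_denominator = zero_den
  )
}
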