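#' Confusion matrix
#'
#' Rows are truth, columns are prediction, in `class_order`.
#'
#' @param truth,predictions equal-length vectors of class labels.
#' @param class_order class levels (default: union, sorted).
#' @return K x K integer matrix with dimnames.
#' @export
confusion_matrix <- function(truth, predictions,
                             class_order = sort(unique(c(truth, predictions)))) {
  abort_if(length(truth) != length(predictions),
           "truth and predictions differ in length")
  t_f <- factor(truth, levels = class_order)
  p_f <- factor(predictions, levels = class_order)
  as.matrix(table(truth = t_f, prediction = p_f))
}

#' Confusion matrix with micro and macro F1
#'
#' Micro F1 pools true/false positives over classes (for single-label
#' multiclass evaluation this equals accuracy); macro F1 is the unweighted
#' mean of the per-class F1 scores. A class absent from both truth and
#' predictions is excluded from the macro average (and noted).
#'
#' @inheritParams confusion_matrix
#' @return list with `confusion`, `per_class_f1`, `micro_f1`, `macro_f1`.
#' @export
confusion_and_f1 <- function(truth, predictions,
                             class_order = sort(unique(c(truth, predictions)))) {
  cm <- confusion_matrix(truth, predictions, class_order)
  K <- nrow(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  f1 <- ifelse(2 * tp + fp + fn > 0, 2 * tp / (2 * tp + fp + fn), NA_real_)
  absent <- rowSums(cm) == 0 & colSums(cm) == 0
  if (any(absent)) {
    message(sprintf("excluding class(es) absent from truth and predictions: %s",
                    paste(rownames(cm)[absent], collapse = ", ")))
    f1[absent] <- NA_real_
  }
  micro <- 2 * sum(tp) / (2 * sum(tp) + sum(fp) + sum(fn))
  list(confusion = cm, per_class_f1 = f1, micro_f1 = micro,
       macro_f1 = mean(f1, na.rm = TRUE))
}

#' Multiclass Matthews correlation coefficient
#'
#' The covariance-based generalization:
#' `(c*s - sum_k p_k t_k) / sqrt((s^2 - sum p_k^2)(s^2 - sum t_k^2))`
#' with `c` the correct count, `s` the total, and `p_k`, `t_k` the
#' prediction and truth marginals. A degenerate marginal returns 0.
#'
#' @param confusion K x K confusion matrix (rows truth, cols prediction).
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(confusion) {
  abort_if(length(confusion) == 0, "empty confusion matrix")
  s <- sum(confusion)
  c_corr <- sum(diag(confusion))
  t_k <- rowSums(confusion)
  p_k <- colSums(confusion)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (den == 0) return(0)
  (c_corr * s - sum(p_k * t_k)) / den
}

#' ROC area under the curve
#'
#' The probability that a random positive outranks a random negative, with
#' ties counted one half (rank / Mann-Whitney formulation; identical to
#' trapezoidal integration of the ROC curve).
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (1/TRUE = positive); both classes required.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  abort_if(n_pos == 0 || n_neg == 0, "both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Sensitivity and specificity from a confusion matrix
#'
#' Binary reduction against one positive class: `sens = TP / (TP + FN)`,
#' `spec = TN / (TN + FP)`. Empty denominators yield `NA`.
#'
#' @param confusion K x K confusion matrix (rows truth, cols prediction).
#' @param positive_class row/column name or index of the positive class.
#' @return list with `sensitivity` and `specificity`.
#' @export
sensitivity_specificity <- function(confusion, positive_class) {
  if (is.character(positive_class)) {
    positive_class <- match(positive_class, rownames(confusion))
  }
  tp <- confusion[positive_class, positive_class]
  fn <- sum(confusion[positive_class, ]) - tp
  fp <- sum(confusion[, positive_class]) - tp
  tn <- sum(confusion) - tp - fn - fp
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' The exact interval from Beta quantiles: lower bound
#' `qbeta(alpha/2, x, n - x + 1)` (0 when x = 0), upper bound
#' `qbeta(1 - alpha/2, x + 1, n - x)` (1 when x = n). Reported as
#' percentages; `display` rounds half-up to integer percent, e.g.
#' 10 of 13 gives 77% (46%-95%).
#'
#' @param successes,trials counts with `0 <= successes <= trials`.
#' @param level confidence level in (0, 1), default 0.95.
#' @return a `BinomialAgreement`: list with `successes`, `trials`,
#'   `point_pct`, `ci_low_pct`, `ci_high_pct`, and rounded `display`.
#' @export
clopper_pearson_ci <- function(successes, trials, level = 0.95) {
  abort_if(level <= 0 || level >= 1, "level must be in (0, 1)")
  abort_if(trials < 1 || successes < 0 || successes > trials,
           "need 0 <= successes <= trials, trials >= 1")
  alpha <- 1 - level
  lo <- if (successes == 0) 0 else stats::qbeta(alpha / 2, successes,
                                                trials - successes + 1)
  hi <- if (successes == trials) 1 else stats::qbeta(1 - alpha / 2,
                                                     successes + 1,
                                                     trials - successes)
  point <- successes / trials
  structure(list(successes = successes, trials = trials,
                 point_pct = 100 * point, ci_low_pct = 100 * lo,
                 ci_high_pct = 100 * hi,
                 display = sprintf("%d%% (%d%%-%d%%)",
                                   round_half_up(100 * point),
                                   round_half_up(100 * lo),
                                   round_half_up(100 * hi))),
            class = "BinomialAgreement")
}

#' Duplicate-core agreement report
#'
#' For a tissue microarray with repeated cores per patient, computes
#' (a) the intra-patient match rate (all cores of a patient predicted the
#' same class) over multi-core patients, (b) among those matched patients,
#' agreement of the unanimous call with the reference label, and (c)
#' consensus-call agreement with the reference over all patients — each
#' with an exact binomial interval.
#'
#' @param patient_ids patient identifier per core.
#' @param core_calls predicted class per core.
#' @param reference named vector: reference (e.g. pathologist) label per
#'   patient.
#' @param consensus_calls optional named vector of per-patient consensus
#'   calls; defaults to the modal core call per patient.
#' @param level confidence level.
#' @return list with `intra_patient`, `matched_vs_reference`,
#'   `consensus_vs_reference` (`BinomialAgreement` or `NULL` when
#'   undefined).
#' @export
duplicate_agreement <- function(patient_ids, core_calls, reference,
                                consensus_calls = NULL, level = 0.95) {
  by_pat <- split(as.character(core_calls), patient_ids)
  multi <- names(by_pat)[lengths(by_pat) >= 2]
  intra <- NULL
  matched_ref <- NULL
  if (length(multi) > 0) {
    agree <- vapply(by_pat[multi], function(v) length(unique(v)) == 1,
                    logical(1))
    intra <- clopper_pearson_ci(sum(agree), length(agree), level)
    m <- multi[agree]
    if (length(m) > 0) {
      hit <- vapply(m, function(p) by_pat[[p]][1] == reference[[p]], logical(1))
      matched_ref <- clopper_pearson_ci(sum(hit), length(m), level)
    }
  } else {
    message("no multi-core patients: intra-patient rate undefined")
  }
  if (is.null(consensus_calls)) {
    consensus_calls <- vapply(by_pat, function(v) {
      names(sort(table(v), decreasing = TRUE))[1]
    }, character(1))
  }
  pats <- names(by_pat)
  hit_c <- vapply(pats, function(p) consensus_calls[[p]] == reference[[p]],
                  logical(1))
  list(intra_patient = intra, matched_vs_reference = matched_ref,
       consensus_vs_reference = clopper_pearson_ci(sum(hit_c), length(pats),
                                                   level))
}
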