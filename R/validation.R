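## k-fold cross-validation, confusion metrics, Mann-Whitney AUC, and the
## chi-square comparison of two classification proportions.

#' Stratified fold assignment
#'
#' Seeded shuffling within each class, then round-robin assignment, so every
#' fold's class ratio is within one subject of the cohort's.
#'
#' @param labels integer 0/1 vector.
#' @param k number of folds.
#' @param seed integer RNG seed.
#' @param stratified stratify by class (default TRUE).
#' @return integer vector of fold ids in 1..k.
#' @export
makeFolds <- function(labels, k, seed = 1L, stratified = TRUE) {
  n <- length(labels)
  set.seed(seed)
  fold <- integer(n)
  if (stratified) {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    fold[sample.int(n)] <- rep_len(seq_len(k), n)
  }
  fold
}

.performanceReport <- function(ids, labels, scores, folds, k, seed) {
  pred <- classifyScore(scores)
  cc <- c(tp = sum(pred == 1L & labels == 1L),
          fn = sum(pred == 0L & labels == 1L),
          tn = sum(pred == 0L & labels == 0L),
          fp = sum(pred == 1L & labels == 0L))
  m <- metricsFromConfusion(cc["tp"], cc["fn"], cc["tn"], cc["fp"])
  auc <- if (length(unique(labels)) == 2L) aucScore(scores, labels)
         else NA_real_
  new("PerformanceReport",
      confusion = setNames(as.integer(cc), names(cc)),
      sensitivity = m$sensitivity, specificity = m$specificity,
      accuracy = m$accuracy, auc = auc,
      perSubject = data.frame(subject_id = ids, label = labels,
                              score = as.numeric(scores), predicted = pred,
                              fold = folds),
      k = as.integer(k), seed = as.integer(seed))
}

#' k-fold cross-validated performance
#'
#' Every subject is scored exactly once, by a model trained without it;
#' metrics come from the single pooled out-of-fold confusion table.  Folds
#' are stratified by class (the class ratio per fold is within one subject);
#' if a class has fewer members than \code{k}, \code{k} is reduced with a
#' warning.
#'
#' @param features a [PetFeatureSet-class].
#' @param params an [SvmParams-class].
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold shuffle.
#' @param stratified stratify folds by class (default TRUE).
#' @return A [PerformanceReport-class].
#' @export
kfoldScores <- function(features, params = svmParams(), k = 10L,
                        seed = 1L, stratified = TRUE) {
  stopifnot(is(features, "PetFeatureSet"))
  y01 <- subjectLabels(features)
  n <- length(y01)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k exceeds the number of subjects")
  if (length(unique(y01)) < 2L) stop("both classes must be present")
  minClass <- min(table(y01))
  if (stratified && minClass < k) {
    warning(sprintf("reducing k from %d to %d (smallest class size)",
                    k, minClass))
    k <- minClass
  }
  folds <- makeFolds(y01, k, seed = seed, stratified = stratified)
  X <- featureMatrix(features)
  K <- .gramMatrix(X, params)
  scores <- numeric(n)
  for (f in seq_len(k)) {
    test <- which(folds == f)
    train <- which(folds != f)
    fit <- .fitHyperplane(X, y01, K, params, subset = train)
    scores[test] <- as.numeric(X[test, , drop = FALSE] %*% fit$weights) +
      fit$bias
  }
  .performanceReport(subjectIds(features), y01, scores, folds, k, seed)
}

#' Confusion-derived rates
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), accuracy
#' (tp+tn)/total, with converters (label 1) as positives.  A rate with a
#' zero denominator is returned as NA (undefined), never as NaN.
#'
#' @param tp,fn,tn,fp nonnegative integer counts.
#' @return list(sensitivity, specificity, accuracy).
#' @export
metricsFromConfusion <- function(tp, fn, tn, fp) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  total <- tp + fn + tn + fp
  if (total == 0) stop("empty confusion table")
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       accuracy = (tp + tn) / total)
}

#' Mann-Whitney AUC
#'
#' The probability that a random positive outscores a random negative, with
#' ties counted one half; computed from midranks.
#'
#' @param scores numeric vector.
#' @param labels integer 0/1 vector (1 = positive).
#' @return AUC in [0, 1].
#' @export
aucScore <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  nPos <- sum(labels == 1L)
  nNeg <- sum(labels == 0L)
  if (nPos == 0L || nNeg == 0L) stop("AUC needs both classes present")
  r <- rank(scores)                     # midranks handle ties
  (sum(r[labels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Chi-square comparison of two proportions
#'
#' Pearson chi-square (1 df, no continuity correction) on the 2x2 table
#' \code{[[k1, n1-k1], [k2, n2-k2]]}, comparing success proportions k1/n1
#' and k2/n2 - e.g. the accuracies of two classifiers on different samples.
#'
#' @param k1,n1 successes and size of group 1 (0 <= k1 <= n1, n1 >= 1).
#' @param k2,n2 successes and size of group 2.
#' @return list(statistic, df, p.value, table).
#' @export
compareProportionsChi2 <- function(k1, n1, k2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  tab <- matrix(c(k1, k2, n1 - k1, n2 - k2), 2, 2,
                dimnames = list(group = c("g1", "g2"),
                                outcome = c("success", "failure")))
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = unname(ht$p.value), table = tab)
}
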