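## Frozen-model application to external cohorts, the paired medication-state
## score test, and label agreement counting.

#' Apply a frozen model to an external cohort
#'
#' Preprocesses the cohort with the model's own training pipeline (same
#' smoothing FWHM, scaling target and mask), scores and labels every
#' subject, and reports the proportion classified as converter.  Any
#' grid or normalization mismatch is a hard error - a frozen classifier
#' never silently changes its preprocessing.
#'
#' @param model a [HyperplaneModel-class].
#' @param cohort a [PetCohort-class] on the model's grid.
#' @param mask optional [BrainMask-class] override; defaults to the cohort's
#'   mask, which must match the model's training mask fingerprint.
#' @return list with \code{perSubject} (data.frame id, score, label),
#'   \code{proportionConverter}, \code{n}.
#' @export
applyToCohort <- function(model, cohort, mask = NULL) {
  stopifnot(is(model, "HyperplaneModel"), is(cohort, "PetCohort"))
  if (is.null(mask)) mask <- cohort@mask
  nr <- model@normalization
  feats <- vectorizeCohort(cohort, mask = mask,
                           fwhm = nr$fwhm_mm, target = nr$target)
  scores <- subjectScores(model, feats)   # enforces the normalization record
  labels <- classifyScore(scores)
  list(perSubject = data.frame(subject_id = subjectIds(cohort),
                               score = as.numeric(scores),
                               label = labels),
       proportionConverter = mean(labels == 1L),
       n = length(labels))
}

#' Paired score test between two conditions
#'
#' Classical paired t test on per-subject score differences
#' (\code{scoresA - scoresB}): \code{t = mean(d) / (sd(d) / sqrt(n))} with
#' \code{n - 1} degrees of freedom and a two-sided p-value.  Zero variance
#' of the differences (e.g. identical score vectors) is flagged as
#' undefined rather than propagated as NaN.
#'
#' @param scoresA,scoresB equal-length numeric vectors, paired by subject
#'   (n >= 2).
#' @return list(t, df, p, meanDifference, undefined).
#' @export
pairedScoreTest <- function(scoresA, scoresB) {
  if (length(scoresA) != length(scoresB))
    stop("score vectors must have equal length")
  n <- length(scoresA)
  if (n < 2L) stop("need at least 2 pairs")
  d <- scoresA - scoresB
  sdD <- sd(d)
  if (sdD == 0)
    return(list(t = NA_real_, df = n - 1L, p = NA_real_,
                meanDifference = mean(d), undefined = TRUE))
  tStat <- mean(d) / (sdD / sqrt(n))
  list(t = tStat, df = n - 1L,
       p = 2 * pt(-abs(tStat), df = n - 1),
       meanDifference = mean(d), undefined = FALSE)
}

#' Label agreement between two classifications
#'
#' @param labelsA,labelsB equal-length label vectors.
#' @return c(nAgree, nTotal).
#' @export
labelAgreement <- function(labelsA, labelsB) {
  if (length(labelsA) != length(labelsB))
    stop("label vectors must have equal length")
  c(nAgree = sum(labelsA == labelsB), nTotal = length(labelsA))
}
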