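## Label-permutation inference on the voxel weight map: the null is built by
## retraining the full model (identical parameters, including trimming) on
## uniformly shuffled class labels; the per-voxel p-value is the proportion
## of null models whose absolute voxel weight reaches the true model's.

#' Permutation null of voxel weights
#'
#' Trains the true model, then \code{nPermutations} models on label-shuffled
#' copies of the data (class sizes preserved), accumulating for each voxel
#' the count of permuted models with \code{|w_perm| >= |w_true|} (ties count
#' as exceedances by default, so the smallest attainable p is 1/n when a tie
#' occurs; set \code{ties = "gt"} for the strict-inequality variant).  The
#' Gram matrix is computed once and shared by all refits.  A permutation
#' whose fit fails is recorded and excluded.
#'
#' @param features a [PetFeatureSet-class].
#' @param params an [SvmParams-class].
#' @param nPermutations number of label permutations (>= 1).  10,000 is the
#'   production setting; a few hundred is adequate for calibration checks.
#' @param seed integer RNG seed for the shuffles.
#' @param ties "geq" (default, conservative) or "gt".
#' @param normalizeWeights compare weight maps after unit L2 normalization
#'   (default TRUE).  The global norm of a soft-margin solution reflects the
#'   achieved margin, not the topography: a cleanly separable training set
#'   yields a much smaller ||w|| than its inseparable label-permuted
#'   counterparts, and the raw-magnitude comparison then loses all power.
#'   Normalization makes the comparison scale-free and is
#'   calibration-preserving under the null (exchangeability); set FALSE for
#'   the raw-magnitude comparison, which coincides with the normalized one
#'   whenever true and null models have matching scales.
#' @param permutations optional integer matrix (nPermutations x n) of
#'   explicit subject orderings to use instead of random shuffles (testing
#'   hook; row \code{1:n} is the identity permutation).
#' @return list with elements \code{trueModel} ([HyperplaneModel-class]),
#'   \code{exceedance} (integer per voxel), \code{nEffective},
#'   \code{nFailed}, \code{nPermutations}, \code{ties}, \code{seed}.
#' @export
permutationNull <- function(features, params = svmParams(),
                            nPermutations = 200L, seed = 1L,
                            ties = c("geq", "gt"), normalizeWeights = TRUE,
                            permutations = NULL) {
  ties <- match.arg(ties)
  stopifnot(nPermutations >= 1L)
  trueModel <- trainSvm(features, params)
  X <- featureMatrix(features)
  y01 <- subjectLabels(features)
  n <- length(y01)
  K <- .gramMatrix(X, params)
  .unitAbs <- function(w) {
    nw <- sqrt(sum(w^2))
    if (normalizeWeights && nw > 0) abs(w) / nw else abs(w)
  }
  absTrue <- .unitAbs(trueModel@weights)
  exceed <- integer(length(absTrue))
  nFailed <- 0L
  nEffective <- 0L
  if (!is.null(permutations)) {
    stopifnot(ncol(permutations) == n)
    nPermutations <- nrow(permutations)
  }
  set.seed(seed)
  for (r in seq_len(nPermutations)) {
    ord <- if (is.null(permutations)) sample.int(n) else permutations[r, ]
    yPerm <- y01[ord]
    fit <- tryCatch(.fitHyperplane(X, yPerm, K, params),
                    error = function(e) NULL)
    if (is.null(fit)) { nFailed <- nFailed + 1L; next }
    nEffective <- nEffective + 1L
    aw <- .unitAbs(fit$weights)
    exceed <- exceed + if (ties == "geq") (aw >= absTrue) else (aw > absTrue)
  }
  if (nFailed > 0L)
    warning(sprintf("%d of %d permutation fits failed and were excluded",
                    nFailed, nPermutations))
  if (nEffective < 1L) stop("no permutation fit succeeded")
  list(trueModel = trueModel, exceedance = exceed,
       nEffective = nEffective, nFailed = nFailed,
       nPermutations = as.integer(nPermutations), ties = ties,
       normalizeWeights = normalizeWeights, seed = as.integer(seed))
}

#' Per-voxel p-values from exceedance counts
#'
#' \code{p_v = exceedance_v / nEffective} (plain proportion); with
#' \code{smoothing = TRUE} the (b+1)/(n+1) estimator is used instead.
#' Voxels with \code{p < alpha} enter the signed significance map with the
#' sign of the true weight.
#'
#' @param model the true [HyperplaneModel-class].
#' @param exceedance integer vector of per-voxel exceedance counts.
#' @param nEffective number of effective permutations (>= 1).
#' @param alpha significance threshold in (0, 1), default 0.05.
#' @param smoothing use the add-one (b+1)/(n+1) estimator (default FALSE).
#' @param seed integer recorded in the map.
#' @return A [VoxelPValueMap-class].
#' @export
voxelPValuesFromCounts <- function(model, exceedance, nEffective,
                                   alpha = 0.05, smoothing = FALSE,
                                   seed = NA_integer_) {
  stopifnot(is(model, "HyperplaneModel"), nEffective >= 1)
  if (any(exceedance > nEffective))
    stop("exceedance count exceeds the number of effective permutations")
  if (length(exceedance) != length(model@weights))
    stop("exceedance length does not match the weight map")
  p <- if (smoothing) (exceedance + 1) / (nEffective + 1)
       else exceedance / nEffective
  sig <- ifelse(p < alpha, sign(model@weights), 0)
  new("VoxelPValueMap", p = p, exceedance = as.integer(exceedance),
      nPermutations = as.integer(nEffective),
      nEffective = as.integer(nEffective), alpha = alpha,
      signedSignificant = as.integer(sig),
      voxelIndex = model@voxelIndex, gridDim = model@gridDim,
      voxelSize = model@voxelSize, seed = as.integer(seed))
}

#' Per-voxel p-values from a permutation run
#'
#' Convenience wrapper applying [voxelPValuesFromCounts()] to the result of
#' [permutationNull()].
#'
#' @param null result of [permutationNull()].
#' @param alpha significance threshold (default 0.05).
#' @param smoothing add-one estimator flag (default FALSE).
#' @return A [VoxelPValueMap-class].
#' @export
voxelPValues <- function(null, alpha = 0.05, smoothing = FALSE) {
  pm <- voxelPValuesFromCounts(null$trueModel, null$exceedance,
                               null$nEffective, alpha = alpha,
                               smoothing = smoothing, seed = null$seed)
  pm@nPermutations <- null$nPermutations
  pm
}

#' Thresholded signed pattern map
#'
#' The conversion-pattern volume: equal to the true voxel weight where
#' \code{p < alpha}, zero elsewhere.  Positive values mark relative
#' hypermetabolism predictive of conversion, negative values relative
#' hypometabolism.
#'
#' @param pmap a [VoxelPValueMap-class].
#' @param model the true [HyperplaneModel-class] the map belongs to.
#' @param alpha threshold in (0, 1]; defaults to the map's alpha (alpha = 1
#'   keeps every voxel with p < 1).
#' @return A [BrainVolume-class] on the model grid.
#' @export
thresholdPattern <- function(pmap, model, alpha = pmap@alpha) {
  stopifnot(is(pmap, "VoxelPValueMap"), is(model, "HyperplaneModel"))
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (!identical(pmap@gridDim, model@gridDim) ||
      length(pmap@p) != length(model@weights))
    stop("p-value map and model grids differ")
  vals <- ifelse(pmap@p < alpha, model@weights, 0)
  grid <- array(FALSE, model@gridDim)
  grid[model@voxelIndex] <- TRUE
  scatterToVolume(vals, brainMask(grid, model@voxelSize))
}

#' Dice overlap of two voxel sets
#'
#' \code{2|A & B| / (|A| + |B|)} between two logical arrays or index sets;
#' the parameter-recovery metric for planted-effect simulations.
#'
#' @param a,b logical arrays/vectors of equal length.
#' @return Dice coefficient in [0, 1] (NaN if both sets are empty).
#' @export
diceOverlap <- function(a, b) {
  stopifnot(length(a) == length(b))
  2 * sum(a & b) / (sum(a) + sum(b))
}
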