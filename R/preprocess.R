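## Image conditioning: separable Gaussian smoothing, proportional (global
## mean) intensity scaling, and vectorization into the feature container.

## Per-axis smoothing matrix: truncated Gaussian rows renormalized to sum 1,
## so a constant field is preserved exactly, including at the grid boundary.
.smoothingMatrix <- function(n, sigmaVox) {
  if (sigmaVox <= 0) return(diag(n))
  halfWidth <- max(1L, ceiling(4 * sigmaVox))
  d <- outer(seq_len(n), seq_len(n), `-`)
  S <- exp(-d^2 / (2 * sigmaVox^2))
  S[abs(d) > halfWidth] <- 0
  S / rowSums(S)
}

.applyAxis1 <- function(arr, S) {
  d <- dim(arr)
  array(S %*% matrix(arr, d[1], d[2] * d[3]), d)
}

#' Separable Gaussian smoothing
#'
#' Convolves a volume with an axis-separable Gaussian of the given FWHM in
#' mm; per-axis sigma (in voxels) is \code{fwhm / (2*sqrt(2*log(2))) /
#' voxelSize}.  Boundary handling is truncated-kernel renormalization, so a
#' constant field maps to itself everywhere.
#'
#' @param vol a [BrainVolume-class].
#' @param fwhm full width at half maximum, mm (> 0).
#' @return the smoothed [BrainVolume-class].
#' @export
smoothGaussian <- function(vol, fwhm) {
  stopifnot(is(vol, "BrainVolume"))
  if (!is.numeric(fwhm) || fwhm <= 0) stop("fwhm must be positive")
  sigma <- fwhmToSigma(fwhm) / vol@voxelSize
  arr <- vol@data
  d <- dim(arr)
  arr <- .applyAxis1(arr, .smoothingMatrix(d[1], sigma[1]))
  arr <- aperm(.applyAxis1(aperm(arr, c(2, 1, 3)),
                           .smoothingMatrix(d[2], sigma[2])), c(2, 1, 3))
  arr <- aperm(.applyAxis1(aperm(arr, c(3, 2, 1)),
                           .smoothingMatrix(d[3], sigma[3])), c(3, 2, 1))
  brainVolume(arr, vol@voxelSize, vol@affine)
}

#' FWHM to Gaussian sigma
#'
#' @param fwhm full width at half maximum (any length unit).
#' @return sigma = fwhm / (2 * sqrt(2 * log(2))), same unit.
#' @export
fwhmToSigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Proportional (global-mean) intensity scaling
#'
#' Rescales a volume so that its mean over the brain mask equals
#' \code{target}: \code{out = vol * target / mean(vol[mask])}.  Removes any
#' subject-level multiplicative global factor (tracer dose / uptake).
#'
#' @param vol a [BrainVolume-class].
#' @param mask a [BrainMask-class] on the same grid.
#' @param target positive target mean (default 50, the conventional
#'   proportional-scaling grand mean).
#' @return the scaled [BrainVolume-class].
#' @export
proportionalScale <- function(vol, mask, target = 50) {
  stopifnot(is(vol, "BrainVolume"), is(mask, "BrainMask"), target > 0)
  if (!identical(dim(vol@data), dim(mask@data)))
    stop("volume and mask grids differ")
  m <- mean(vol@data[mask@data])
  if (!is.finite(m) || m <= 0)
    stop(sprintf("nonpositive whole-brain mean (%.4g): empty or pathological scan", m))
  brainVolume(vol@data * (target / m), vol@voxelSize, vol@affine)
}

#' Preprocess a cohort into a feature container
#'
#' Each subject volume is smoothed (FWHM \code{fwhm} mm), proportionally
#' scaled to mean \code{target} over the mask, and flattened over the mask
#' voxels in ascending linear-index order.  The order of operations
#' (smooth, then scale) and the normalization record are fixed properties of
#' the container; a frozen model refuses features with a different record.
#'
#' @param cohort a [PetCohort-class].
#' @param mask [BrainMask-class]; defaults to the cohort's own mask.
#' @param fwhm smoothing FWHM in mm (default 8).
#' @param target proportional-scaling target mean (default 50).
#' @return A [PetFeatureSet-class] (voxels x subjects).
#' @export
vectorizeCohort <- function(cohort, mask = NULL, fwhm = 8, target = 50) {
  stopifnot(is(cohort, "PetCohort"))
  if (is.null(mask)) mask <- cohort@mask
  if (length(cohort@volumes) == 0L) stop("empty cohort")
  if (!identical(dim(cohort@volumes[[1]]@data), dim(mask@data)))
    stop("cohort grid does not match the mask grid")
  idx <- .maskVoxelIndex(mask)
  vals <- vapply(cohort@volumes, function(v) {
    proportionalScale(smoothGaussian(v, fwhm), mask, target)@data[idx]
  }, numeric(nrow(idx)))
  colnames(vals) <- cohort@subjectIds
  record <- list(fwhm_mm = fwhm, target = target,
                 mask = maskFingerprint(mask),
                 voxel_size_mm = mask@voxelSize,
                 order = "smooth-then-scale")
  petFeatureSet(vals, idx, cohort@subjectIds, cohort@labels, record)
}

#' Assemble a feature container from a matrix
#'
#' Low-level constructor used by [vectorizeCohort()]; also handy for building
#' feature sets directly from an externally prepared voxels-by-subjects
#' matrix.
#'
#' @param values numeric matrix, voxels (rows) by subjects (columns).
#' @param voxelIndex integer matrix (nVoxels x 3) of (i,j,k) indices.
#' @param subjectIds character vector of unique subject ids.
#' @param labels integer 0/1 class labels.
#' @param normalization the normalization record list (fwhm_mm, target,
#'   mask fingerprint, voxel_size_mm).
#' @return A [PetFeatureSet-class].
#' @export
petFeatureSet <- function(values, voxelIndex, subjectIds, labels,
                          normalization) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(uptake = values),
    rowData = S4Vectors::DataFrame(i = voxelIndex[, 1], j = voxelIndex[, 2],
                                   k = voxelIndex[, 3]),
    colData = S4Vectors::DataFrame(subject_id = subjectIds,
                                   label = as.integer(labels),
                                   row.names = subjectIds),
    metadata = list(normalization = normalization))
  new("PetFeatureSet", se)
}
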