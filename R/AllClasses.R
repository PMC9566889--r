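#' @import methods
#' @importFrom stats rnorm rlnorm sd pt fft setNames cor
#' @importFrom utils read.csv write.csv
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

## Central S4 containers.  Conventions:
##  - class label is integer 0/1, 1 = "converter" (carries the planted /
##    disease effect, scores positive), 0 = "stable".
##  - voxel order everywhere is the ascending linear index of the mask grid
##    (column-major, i fastest), recorded explicitly as an (i,j,k) index map.

#' Brain volume
#'
#' A 3-D scalar field of tracer uptake with voxel-size metadata and a
#' voxel-to-world affine.  The unit of all image I/O and preprocessing.
#'
#' @slot data 3-D numeric array of finite intensities.
#' @slot voxelSize numeric(3), voxel edge lengths in mm (all > 0).
#' @slot affine 4x4 voxel-index-to-world-mm matrix (carried through I/O,
#'   never used for resampling).
#' @export
setClass("BrainVolume",
  representation(data = "array", voxelSize = "numeric", affine = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3-D array")
    nbad <- sum(!is.finite(object@data))
    if (nbad > 0L)
      msg <- c(msg, sprintf("%d non-finite voxel(s) in volume", nbad))
    if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
        any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be 3 positive reals")
    if (!all(dim(object@affine) == c(4L, 4L)))
      msg <- c(msg, "affine must be 4x4")
    if (length(msg)) msg else TRUE
  })

#' Binary brain mask
#'
#' The "whole brain" region over which the scaling mean is taken and inside
#' which voxels enter the feature matrix.
#'
#' @slot data 3-D logical array with at least one TRUE voxel.
#' @slot voxelSize numeric(3) as in [BrainVolume-class].
#' @slot affine 4x4 affine as in [BrainVolume-class].
#' @export
setClass("BrainMask",
  representation(data = "array", voxelSize = "numeric", affine = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L || !is.logical(object@data))
      msg <- c(msg, "mask data must be a 3-D logical array")
    else if (!any(object@data))
      msg <- c(msg, "mask has no TRUE voxel")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be 3 positive reals")
    if (length(msg)) msg else TRUE
  })

#' Labeled cohort of volumes
#'
#' An ordered collection of labeled subject volumes sharing one grid and one
#' brain mask.
#'
#' @slot volumes list of [BrainVolume-class], all on the mask's grid.
#' @slot subjectIds character vector of unique ids, aligned to volumes.
#' @slot labels integer vector in \{0, 1\} (1 = converter-like).
#' @slot mask [BrainMask-class].
#' @slot provenance list; simulation configuration or an acquisition note.
#' @export
setClass("PetCohort",
  representation(volumes = "list", subjectIds = "character",
                 labels = "integer", mask = "BrainMask",
                 provenance = "list"),
  validity = function(object) {
    msg <- character()
    n <- length(object@volumes)
    if (length(object@subjectIds) != n || length(object@labels) != n)
      msg <- c(msg, "subjectIds/labels length must match volumes")
    if (anyDuplicated(object@subjectIds))
      msg <- c(msg, "subject ids must be unique")
    if (n && !all(object@labels %in% c(0L, 1L)))
      msg <- c(msg, "labels must be 0/1")
    md <- dim(object@mask@data)
    for (v in object@volumes)
      if (!identical(dim(v@data), md)) {
        msg <- c(msg, "all volumes must share the mask's grid")
        break
      }
    if (length(msg)) msg else TRUE
  })

#' Subjects-by-voxels feature matrix
#'
#' The preprocessed (smoothed, proportionally scaled, masked) data entering
#' the classifier, stored as a \linkS4class{SummarizedExperiment} with one
#' assay of mask voxels (rows) by subjects (columns).  \code{rowData} holds
#' the (i,j,k) voxel index of each row; \code{colData} holds subject ids and
#' class labels; \code{metadata(x)$normalization} records the smoothing FWHM,
#' scaling target and mask fingerprint so that a frozen model can refuse
#' inputs preprocessed differently.
#'
#' @export
setClass("PetFeatureSet", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- character()
    if (!"uptake" %in% SummarizedExperiment::assayNames(object))
      msg <- c(msg, "assay 'uptake' missing")
    rd <- SummarizedExperiment::rowData(object)
    if (!all(c("i", "j", "k") %in% colnames(rd)))
      msg <- c(msg, "rowData must carry voxel indices i,j,k")
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("subject_id", "label") %in% colnames(cd)))
      msg <- c(msg, "colData must carry subject_id and label")
    nr <- S4Vectors::metadata(object)$normalization
    if (is.null(nr))
      msg <- c(msg, "metadata$normalization missing")
    if (length(msg)) msg else TRUE
  })

#' Soft-margin linear classifier parameters
#'
#' Mirrors the training contract of a linear-kernel soft-margin SVM:
#' kernel k(x, y) = (x.y)/kernelScale^2 + kernelOffset, per-class
#' misclassification costs, an outlier fraction excluded by slack trimming,
#' and solver controls.
#'
#' @slot outlierFraction real in [0, 1); fraction of largest-slack training
#'   points dropped before a single refit (0 = plain SVM).
#' @slot cost 2x2 nonnegative matrix with zero diagonal; \code{cost[a+1, b+1]}
#'   is the cost of predicting class b for true class a.
#' @slot kernelOffset nonnegative constant added to every inner product.
#' @slot kernelScale positive scale divisor of the inner product.
#' @slot maxIterations positive integer cap on solver iterations.
#' @slot tolerance positive KKT violation tolerance.
#' @slot boxConstraint positive base box constraint C.
#' @slot seed integer; recorded for provenance (the solver is deterministic).
#' @export
setClass("SvmParams",
  representation(outlierFraction = "numeric", cost = "matrix",
                 kernelOffset = "numeric", kernelScale = "numeric",
                 maxIterations = "numeric", tolerance = "numeric",
                 boxConstraint = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@outlierFraction < 0 || object@outlierFraction >= 1)
      msg <- c(msg, "outlierFraction must be in [0, 1)")
    if (!all(dim(object@cost) == 2L) || any(object@cost < 0) ||
        any(diag(object@cost) != 0))
      msg <- c(msg, "cost must be 2x2, nonnegative, zero diagonal")
    if (object@kernelOffset < 0) msg <- c(msg, "kernelOffset must be >= 0")
    if (object@kernelScale <= 0) msg <- c(msg, "kernelScale must be > 0")
    if (object@maxIterations < 1) msg <- c(msg, "maxIterations must be >= 1")
    if (object@tolerance <= 0) msg <- c(msg, "tolerance must be > 0")
    if (object@boxConstraint <= 0) msg <- c(msg, "boxConstraint must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Trained voxel-wise hyperplane
#'
#' The linear decision function of the classifier: one weight per mask voxel
#' plus a bias, so that a subject's score is \code{sum(w * x) + b} and the
#' predicted class is 1 iff the score is positive.
#'
#' @slot weights numeric vector, one finite weight per mask voxel.
#' @slot bias numeric scalar.
#' @slot params [SvmParams-class] used for training.
#' @slot voxelIndex integer matrix (nVoxels x 3) of (i,j,k) mask voxels in
#'   ascending linear-index order.
#' @slot gridDim integer(3) grid of the training mask.
#' @slot voxelSize numeric(3) in mm.
#' @slot normalization list; the preprocessing record scores are valid under.
#' @slot provenance list: class counts, dropped (trimmed) subjects, solver
#'   iteration count, convergence flag, seed.
#' @export
setClass("HyperplaneModel",
  representation(weights = "numeric", bias = "numeric", params = "SvmParams",
                 voxelIndex = "matrix", gridDim = "integer",
                 voxelSize = "numeric", normalization = "list",
                 provenance = "list"),
  validity = function(object) {
    msg <- character()
    if (any(!is.finite(object@weights)) || !is.finite(object@bias))
      msg <- c(msg, "weights and bias must be finite")
    if (nrow(object@voxelIndex) != length(object@weights))
      msg <- c(msg, "voxelIndex rows must match weight count")
    if (length(msg)) msg else TRUE
  })

#' Per-voxel permutation p-values
#'
#' Permutation p-values for each voxel weight of a trained model, with the
#' signed map of voxels surviving the threshold (sign of the true weight).
#'
#' @slot p numeric vector in [0, 1], one per mask voxel.
#' @slot exceedance integer vector of null exceedance counts.
#' @slot nPermutations integer, permutations requested.
#' @slot nEffective integer, permutations that produced a model.
#' @slot alpha threshold in (0, 1).
#' @slot signedSignificant integer vector in \{-1, 0, +1\}.
#' @slot voxelIndex,gridDim,voxelSize grid bookkeeping as in the model.
#' @slot seed integer.
#' @export
setClass("VoxelPValueMap",
  representation(p = "numeric", exceedance = "integer",
                 nPermutations = "integer", nEffective = "integer",
                 alpha = "numeric", signedSignificant = "integer",
                 voxelIndex = "matrix", gridDim = "integer",
                 voxelSize = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (any(object@p < 0 | object@p > 1)) msg <- c(msg, "p outside [0,1]")
    if (any(object@exceedance > object@nEffective))
      msg <- c(msg, "exceedance count exceeds effective permutations")
    if (object@alpha <= 0 || object@alpha >= 1)
      msg <- c(msg, "alpha must be in (0,1)")
    if (any(object@signedSignificant != 0 & object@p >= object@alpha))
      msg <- c(msg, "signedSignificant nonzero at p >= alpha")
    if (length(msg)) msg else TRUE
  })

#' Cross-validation / classification performance report
#'
#' Pooled out-of-fold confusion counts and derived rates, with the per-subject
#' score table and the fold assignment.  Converters (label 1) are positives.
#'
#' @slot confusion named integer vector (tp, fn, tn, fp).
#' @slot sensitivity,specificity,accuracy reals in [0, 1] (NA when the
#'   denominator is empty).
#' @slot auc Mann-Whitney AUC of the out-of-fold scores (NA if one class
#'   absent).
#' @slot perSubject data.frame: subject_id, label, score, predicted, fold.
#' @slot k integer number of folds (1 for a plain train/test application).
#' @slot seed integer.
#' @export
setClass("PerformanceReport",
  representation(confusion = "integer", sensitivity = "numeric",
                 specificity = "numeric", accuracy = "numeric",
                 auc = "numeric", perSubject = "data.frame",
                 k = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (!all(c("tp", "fn", "tn", "fp") %in% names(object@confusion)))
      msg <- c(msg, "confusion must be named tp,fn,tn,fp")
    else if (any(object@confusion < 0))
      msg <- c(msg, "confusion counts must be nonnegative")
    if (length(msg)) msg else TRUE
  })

#' Spatial similarity test result
#'
#' Pearson spatial correlation between two pattern maps and its two-sided
#' p-value under an autocorrelation-preserving surrogate null.
#'
#' @slot r Pearson correlation over mask voxels.
#' @slot p surrogate p-value in (0, 1].
#' @slot nSurrogates integer.
#' @slot surrogateR numeric vector of surrogate correlations.
#' @slot seed integer.
#' @export
setClass("SimilarityResult",
  representation(r = "numeric", p = "numeric", nSurrogates = "integer",
                 surrogateR = "numeric", seed = "integer"))

## ---- show methods ----------------------------------------------------------

setMethod("show", "BrainVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("BrainVolume %dx%dx%d, voxel %.3gx%.3gx%.3g mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], object@voxelSize[1], object@voxelSize[2],
              object@voxelSize[3], min(object@data), max(object@data)))
})

setMethod("show", "BrainMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("BrainMask %dx%dx%d, %d voxels in mask (%.1f%% of grid)\n",
              d[1], d[2], d[3], sum(object@data),
              100 * mean(object@data)))
})

setMethod("show", "PetCohort", function(object) {
  cat(sprintf("PetCohort: %d subjects (%d converter / %d stable), grid %s\n",
              length(object@volumes), sum(object@labels == 1L),
              sum(object@labels == 0L),
              paste(dim(object@mask@data), collapse = "x")))
})

setMethod("show", "HyperplaneModel", function(object) {
  cat(sprintf("HyperplaneModel: %d voxel weights, bias %.6g\n",
              length(object@weights), object@bias))
  cc <- unlist(object@provenance$classCounts)
  cat(sprintf("  trained on %d subjects (%s), converged: %s\n",
              sum(cc),
              paste(sprintf("%d of class %s", cc, names(cc)),
                    collapse = ", "),
              isTRUE(object@provenance$converged)))
})

setMethod("show", "VoxelPValueMap", function(object) {
  cat(sprintf(
    "VoxelPValueMap: %d voxels, %d/%d effective permutations, alpha %.3g\n",
    length(object@p), object@nEffective, object@nPermutations, object@alpha))
  cat(sprintf("  significant: %d (+), %d (-)\n",
              sum(object@signedSignificant > 0L),
              sum(object@signedSignificant < 0L)))
})

setMethod("show", "PerformanceReport", function(object) {
  cc <- object@confusion
  cat(sprintf("PerformanceReport (k = %d): tp %d fn %d tn %d fp %d\n",
              object@k, cc["tp"], cc["fn"], cc["tn"], cc["fp"]))
  cat(sprintf("  sensitivity %.4f  specificity %.4f  accuracy %.4f  AUC %s\n",
              object@sensitivity, object@specificity, object@accuracy,
              ifelse(is.na(object@auc), "NA", sprintf("%.4f", object@auc))))
})

setMethod("show", "SimilarityResult", function(object) {
  cat(sprintf("SimilarityResult: r = %.4f, p = %.4g (%d surrogates)\n",
              object@r, object@p, object@nSurrogates))
})
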