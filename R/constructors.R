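## Constructors and accessors.

.defaultAffine <- function(voxelSize) {
  a <- diag(c(voxelSize, 1))
  a
}

#' Create a BrainVolume
#'
#' @param data 3-D numeric array of finite intensities.
#' @param voxelSize numeric(3) voxel edge lengths in mm.
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   scaling by \code{voxelSize}.
#' @return A [BrainVolume-class].
#' @export
brainVolume <- function(data, voxelSize = c(1, 1, 1), affine = NULL) {
  if (is.null(affine)) affine <- .defaultAffine(voxelSize)
  new("BrainVolume", data = data, voxelSize = as.numeric(voxelSize),
      affine = affine)
}

#' Create a BrainMask
#'
#' @param data 3-D logical (or coercible 0/1) array.
#' @inheritParams brainVolume
#' @return A [BrainMask-class].
#' @export
brainMask <- function(data, voxelSize = c(1, 1, 1), affine = NULL) {
  if (!is.logical(data)) {
    storage.mode(data) <- "logical"
  }
  if (is.null(affine)) affine <- .defaultAffine(voxelSize)
  new("BrainMask", data = data, voxelSize = as.numeric(voxelSize),
      affine = affine)
}

#' Assemble a labeled cohort
#'
#' @param volumes list of [BrainVolume-class] on the mask's grid.
#' @param subjectIds character vector of unique ids.
#' @param labels integer/numeric vector of 0/1 class labels (1 = converter).
#' @param mask [BrainMask-class].
#' @param provenance free-form list (simulation config or acquisition note).
#' @return A [PetCohort-class].
#' @export
petCohort <- function(volumes, subjectIds, labels, mask,
                      provenance = list()) {
  new("PetCohort", volumes = volumes, subjectIds = as.character(subjectIds),
      labels = as.integer(labels), mask = mask, provenance = provenance)
}

## ---- generics --------------------------------------------------------------

#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))
#' @export
setGeneric("subjectLabels", function(x) standardGeneric("subjectLabels"))
#' @export
setGeneric("cohortMask", function(x) standardGeneric("cohortMask"))
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @export
setGeneric("voxelIndex", function(x) standardGeneric("voxelIndex"))
#' @export
setGeneric("normalizationRecord",
           function(x) standardGeneric("normalizationRecord"))
#' @export
setGeneric("modelWeights", function(x) standardGeneric("modelWeights"))
#' @export
setGeneric("modelBias", function(x) standardGeneric("modelBias"))
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))
#' @export
setGeneric("patternSigns", function(x) standardGeneric("patternSigns"))
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))
#' @export
setGeneric("perSubjectScores", function(x) standardGeneric("perSubjectScores"))

#' @describeIn BrainVolume-class the raw 3-D array
#' @param x object
#' @export
setMethod("voxelData", "BrainVolume", function(x) x@data)
#' @describeIn BrainMask-class the 3-D logical array
#' @param x object
#' @export
setMethod("voxelData", "BrainMask", function(x) x@data)
#' @export
setMethod("voxelSize", "BrainVolume", function(x) x@voxelSize)
#' @export
setMethod("voxelSize", "BrainMask", function(x) x@voxelSize)

#' @export
setMethod("subjectIds", "PetCohort", function(x) x@subjectIds)
#' @export
setMethod("subjectLabels", "PetCohort", function(x) x@labels)
#' @export
setMethod("cohortMask", "PetCohort", function(x) x@mask)
#' @export
setMethod("length", "PetCohort", function(x) length(x@volumes))

#' Extract one subject's volume
#' @param x a [PetCohort-class]
#' @param i index
#' @param j,... unused
#' @export
setMethod("[[", "PetCohort", function(x, i, j, ...) x@volumes[[i]])

#' @export
setMethod("subjectIds", "PetFeatureSet",
          function(x) as.character(SummarizedExperiment::colData(x)$subject_id))
#' @export
setMethod("subjectLabels", "PetFeatureSet",
          function(x) as.integer(SummarizedExperiment::colData(x)$label))
#' @describeIn PetFeatureSet-class the subjects-by-voxels matrix
#' @param x object
#' @export
setMethod("featureMatrix", "PetFeatureSet",
          function(x) t(SummarizedExperiment::assay(x, "uptake")))
#' @export
setMethod("voxelIndex", "PetFeatureSet", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  cbind(i = rd$i, j = rd$j, k = rd$k)
})
#' @export
setMethod("normalizationRecord", "PetFeatureSet",
          function(x) S4Vectors::metadata(x)$normalization)

#' @export
setMethod("modelWeights", "HyperplaneModel", function(x) x@weights)
#' @export
setMethod("modelBias", "HyperplaneModel", function(x) x@bias)
#' @export
setMethod("voxelIndex", "HyperplaneModel", function(x) x@voxelIndex)
#' @export
setMethod("normalizationRecord", "HyperplaneModel",
          function(x) x@normalization)

#' @export
setMethod("pValues", "VoxelPValueMap", function(x) x@p)
#' @export
setMethod("patternSigns", "VoxelPValueMap", function(x) x@signedSignificant)
#' @export
setMethod("voxelIndex", "VoxelPValueMap", function(x) x@voxelIndex)

#' @export
setMethod("confusionCounts", "PerformanceReport", function(x) x@confusion)
#' @export
setMethod("perSubjectScores", "PerformanceReport", function(x) x@perSubject)

## ---- shared helpers --------------------------------------------------------

## Mask voxels in ascending linear (column-major) order; the single voxel
## ordering used by every module.
.maskVoxelIndex <- function(mask) {
  stopifnot(is(mask, "BrainMask"))
  lin <- which(mask@data)
  idx <- arrayInd(lin, dim(mask@data))
  colnames(idx) <- c("i", "j", "k")
  storage.mode(idx) <- "integer"
  idx
}

## Cheap order-sensitive fingerprint of a mask: grid, count, and a checksum
## of the linear indices.  Used to detect preprocessing mismatches.
maskFingerprint <- function(mask) {
  lin <- which(mask@data)
  list(dim = as.integer(dim(mask@data)),
       nVoxels = length(lin),
       checksum = sum(as.double(lin) * (seq_along(lin) %% 97 + 1)))
}

.sameNormalization <- function(a, b, tol = 1e-9) {
  isTRUE(all.equal(a$fwhm_mm, b$fwhm_mm, tolerance = tol)) &&
    isTRUE(all.equal(a$target, b$target, tolerance = tol)) &&
    identical(a$mask$dim, b$mask$dim) &&
    identical(a$mask$nVoxels, b$mask$nVoxels) &&
    isTRUE(all.equal(a$mask$checksum, b$mask$checksum, tolerance = tol))
}
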