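## NIfTI and model-directory I/O.  NIfTI-1/2 read, NIfTI-1 write via RNifti.
## Images are written float32, masks uint8, weight maps float64 (weight maps
## must reproduce subject scores to 1e-10 relative after a round-trip, which
## float32 cannot guarantee).

.asNiftiImage <- function(data, voxelSize, affine) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- voxelSize
  RNifti::`sform<-`(img, structure(affine, code = 2L))
}

.checkFinite <- function(arr, path) {
  nbad <- sum(!is.finite(arr))
  if (nbad > 0L)
    stop(sprintf("%d non-finite voxel(s) in '%s'", nbad, path))
}

#' Read a 3-D NIfTI volume
#'
#' @param path path to a NIfTI-1/2 file (optionally gzipped).
#' @return A [BrainVolume-class]; voxel size is taken from the header.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected 3-D volume, got %d-D image in '%s'",
                 length(d), path))
  arr <- array(as.numeric(img), d)
  .checkFinite(arr, path)
  vs <- RNifti::pixdim(img)[seq_len(3)]
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  brainVolume(arr, voxelSize = vs, affine = aff)
}

#' Write a volume as NIfTI-1
#'
#' @param vol a [BrainVolume-class].
#' @param path output path (".nii" or ".nii.gz").
#' @param datatype on-disk payload type; default "float" (float32).
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(vol, path, datatype = "float") {
  stopifnot(is(vol, "BrainVolume"))
  img <- .asNiftiImage(vol@data, vol@voxelSize, vol@affine)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a binary brain mask
#'
#' Nonzero voxels are in-mask.
#' @inheritParams readVolume
#' @return A [BrainMask-class].
#' @export
readMask <- function(path) {
  vol <- readVolume(path)
  brainMask(vol@data != 0, voxelSize = vol@voxelSize, affine = vol@affine)
}

#' Write a brain mask as uint8 NIfTI-1
#'
#' @param mask a [BrainMask-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "BrainMask"))
  img <- .asNiftiImage(array(as.integer(mask@data), dim(mask@data)),
                       mask@voxelSize, mask@affine)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Save a trained model directory
#'
#' Writes \code{weights.nii.gz} (float64, on the training mask's grid, zero
#' outside the mask), \code{mask.nii.gz}, and a human-readable
#' \code{model.json} sidecar holding the bias, parameters, normalization
#' record and provenance.  The sidecar records that subject scores include
#' the bias term.
#'
#' @param model a [HyperplaneModel-class].
#' @param dirPath directory to create/populate.
#' @return \code{dirPath}, invisibly.
#' @export
saveModel <- function(model, dirPath) {
  stopifnot(is(model, "HyperplaneModel"))
  dir.create(dirPath, showWarnings = FALSE, recursive = TRUE)
  grid <- array(FALSE, model@gridDim)
  grid[model@voxelIndex] <- TRUE
  mask <- brainMask(grid, voxelSize = model@voxelSize)
  wvol <- scatterToVolume(model@weights, mask)
  writeVolume(wvol, file.path(dirPath, "weights.nii.gz"),
              datatype = "double")
  writeMask(mask, file.path(dirPath, "mask.nii.gz"))
  p <- model@params
  meta <- list(
    format = "petstratify-model-1",
    bias = model@bias,
    score_includes_bias = TRUE,
    n_voxels = length(model@weights),
    grid_dim = model@gridDim,
    voxel_size_mm = model@voxelSize,
    params = list(outlier_fraction = p@outlierFraction,
                  misclassification_cost = p@cost,
                  kernel_offset = p@kernelOffset,
                  kernel_scale = p@kernelScale,
                  max_iterations = p@maxIterations,
                  convergence_tolerance = p@tolerance,
                  box_constraint = p@boxConstraint,
                  seed = p@seed),
    normalization = model@normalization,
    provenance = model@provenance)
  jsonlite::write_json(meta, file.path(dirPath, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dirPath)
}

#' Load a model directory written by [saveModel()]
#'
#' @param dirPath model directory.
#' @return A [HyperplaneModel-class].
#' @export
loadModel <- function(dirPath) {
  jpath <- file.path(dirPath, "model.json")
  if (!file.exists(jpath))
    stop(sprintf("model sidecar missing: '%s'", jpath))
  meta <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  mask <- readMask(file.path(dirPath, "mask.nii.gz"))
  wvol <- readVolume(file.path(dirPath, "weights.nii.gz"))
  if (!identical(dim(wvol@data), dim(mask@data)))
    stop("weight map grid does not match the model mask")
  if (!identical(as.integer(meta$grid_dim), dim(mask@data)))
    stop("mask grid does not match the metadata-declared grid")
  idx <- .maskVoxelIndex(mask)
  if (nrow(idx) != meta$n_voxels)
    stop("mask voxel count does not match the metadata-declared count")
  p <- meta$params
  params <- svmParams(outlierFraction = p$outlier_fraction,
                      cost = matrix(unlist(p$misclassification_cost), 2, 2),
                      kernelOffset = p$kernel_offset,
                      kernelScale = p$kernel_scale,
                      maxIterations = p$max_iterations,
                      tolerance = p$convergence_tolerance,
                      boxConstraint = p$box_constraint,
                      seed = as.integer(p$seed))
  norm <- meta$normalization
  norm$mask$dim <- as.integer(norm$mask$dim)
  norm$mask$nVoxels <- as.integer(norm$mask$nVoxels)
  new("HyperplaneModel",
      weights = wvol@data[idx], bias = meta$bias, params = params,
      voxelIndex = idx, gridDim = dim(mask@data),
      voxelSize = mask@voxelSize, normalization = norm,
      provenance = as.list(meta$provenance))
}

#' Write a cohort to disk
#'
#' Writes per-subject NIfTI volumes, the mask, and a \code{labels.csv}
#' manifest with columns \code{subject_id,label,path}.
#'
#' @param cohort a [PetCohort-class].
#' @param dirPath output directory.
#' @return path of the manifest, invisibly.
#' @export
writeCohort <- function(cohort, dirPath) {
  dir.create(dirPath, showWarnings = FALSE, recursive = TRUE)
  writeMask(cohort@mask, file.path(dirPath, "mask.nii.gz"))
  files <- sprintf("%s.nii.gz", cohort@subjectIds)
  for (s in seq_along(cohort@volumes))
    writeVolume(cohort@volumes[[s]], file.path(dirPath, files[s]))
  manifest <- data.frame(subject_id = cohort@subjectIds,
                         label = cohort@labels, path = files)
  mpath <- file.path(dirPath, "labels.csv")
  write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  invisible(mpath)
}

#' Read a cohort from a manifest
#'
#' @param manifestPath a \code{labels.csv} with columns
#'   \code{subject_id,label,path} (paths relative to the manifest).
#' @param mask optional [BrainMask-class]; defaults to \code{mask.nii.gz}
#'   next to the manifest.
#' @return A [PetCohort-class].
#' @export
readCohort <- function(manifestPath, mask = NULL) {
  manifest <- read.csv(manifestPath, stringsAsFactors = FALSE)
  need <- c("subject_id", "label", "path")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns subject_id,label,path")
  base <- dirname(manifestPath)
  if (is.null(mask)) mask <- readMask(file.path(base, "mask.nii.gz"))
  vols <- lapply(manifest$path, function(p) readVolume(file.path(base, p)))
  petCohort(vols, manifest$subject_id, manifest$label, mask,
            provenance = list(manifest = manifestPath))
}

#' Write a performance report
#'
#' Writes \code{report.json} (confusion counts and rates) and
#' \code{per_subject.csv} (out-of-fold scores) into a directory.
#'
#' @param report a [PerformanceReport-class].
#' @param dirPath output directory.
#' @return \code{dirPath}, invisibly.
#' @export
writePerformanceReport <- function(report, dirPath) {
  dir.create(dirPath, showWarnings = FALSE, recursive = TRUE)
  cc <- report@confusion
  jsonlite::write_json(
    list(confusion = as.list(cc),
         sensitivity = report@sensitivity,
         specificity = report@specificity,
         accuracy = report@accuracy,
         auc = report@auc, k = report@k, seed = report@seed),
    file.path(dirPath, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  write.csv(report@perSubject, file.path(dirPath, "per_subject.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(dirPath)
}

#' Scatter per-voxel values back into a grid volume
#'
#' Inverse of the mask flattening: places \code{values} at the mask's voxels
#' (ascending linear-index order) and zero elsewhere.
#'
#' @param values numeric vector, one value per mask voxel.
#' @param mask a [BrainMask-class].
#' @return A [BrainVolume-class].
#' @export
scatterToVolume <- function(values, mask) {
  idx <- .maskVoxelIndex(mask)
  if (length(values) != nrow(idx))
    stop(sprintf("expected %d values for this mask, got %d",
                 nrow(idx), length(values)))
  arr <- array(0, dim(mask@data))
  arr[idx] <- values
  brainVolume(arr, voxelSize = mask@voxelSize, affine = mask@affine)
}
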