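## Soft-margin linear SVM with the kernel k(x,y) = (x.y)/scale^2 + offset,
## per-class misclassification costs, and robust "outlier fraction" slack
## trimming.  The dual is solved by a deterministic maximal-violating-pair
## SMO (two-variable analytic updates, lowest-index tie-break), so identical
## inputs always give bit-identical weights.  Because the equality constraint
## sum(alpha * y) = 0 holds throughout, the kernel offset contributes nothing
## to the exported primal decision function; it is absorbed exactly.

#' Construct solver parameters
#'
#' Defaults mirror the conventional soft-margin contract for voxel-wise
#' FDG-PET classification: outlier fraction 0.05, symmetric unit cost,
#' kernel offset 0.1, kernel scale 1, at most 1e6 solver iterations.
#'
#' @param outlierFraction fraction in [0, 1) of largest-slack training points
#'   excluded by one trimming refit (0 recovers the plain SVM).
#' @param cost 2x2 misclassification cost matrix, zero diagonal;
#'   row = true class (0, 1), column = predicted class.
#' @param kernelOffset nonnegative constant added to every inner product.
#' @param kernelScale positive divisor of the inner product.
#' @param maxIterations solver iteration cap.
#' @param tolerance KKT violation tolerance for convergence.
#' @param boxConstraint base box constraint C (scaled per class by the cost
#'   of misclassifying that class).
#' @param seed integer, recorded in provenance.
#' @return An [SvmParams-class].
#' @export
svmParams <- function(outlierFraction = 0.05,
                      cost = matrix(c(0, 1, 1, 0), 2, 2),
                      kernelOffset = 0.1, kernelScale = 1,
                      maxIterations = 1e6, tolerance = 1e-8,
                      boxConstraint = 1, seed = 1L) {
  new("SvmParams", outlierFraction = outlierFraction, cost = cost,
      kernelOffset = kernelOffset, kernelScale = kernelScale,
      maxIterations = maxIterations, tolerance = tolerance,
      boxConstraint = boxConstraint, seed = as.integer(seed))
}

## Deterministic SMO on the dual:
##   min  0.5 a' Q a - e' a,  Q = (y y') * K,  0 <= a_i <= C_i,  y' a = 0.
## Working pair = maximal KKT violating pair; ties broken by lowest index
## (which.max/which.min are deterministic).
.solveSvmDual <- function(K, y, C, tol = 1e-8, maxit = 1e6) {
  n <- length(y)
  alpha <- numeric(n)
  G <- rep(-1, n)                       # gradient at alpha = 0
  eps <- 1e-12
  it <- 0L
  converged <- FALSE
  repeat {
    m <- -y * G                         # m_i = y_i - f_i at optimum
    up <- (y > 0 & alpha < C - eps) | (y < 0 & alpha > eps)
    low <- (y > 0 & alpha > eps) | (y < 0 & alpha < C - eps)
    if (!any(up) || !any(low)) { converged <- TRUE; break }
    iu <- which(up); i <- iu[which.max(m[iu])]
    il <- which(low); j <- il[which.min(m[il])]
    if (m[i] - m[j] < tol) { converged <- TRUE; break }
    if (it >= maxit) break
    it <- it + 1L
    quad <- K[i, i] + K[j, j] - 2 * K[i, j]
    tStar <- if (quad > eps) (m[i] - m[j]) / quad else Inf
    tMaxI <- if (y[i] > 0) C[i] - alpha[i] else alpha[i]
    tMaxJ <- if (y[j] > 0) alpha[j] else C[j] - alpha[j]
    tt <- min(tStar, tMaxI, tMaxJ)
    alpha[i] <- alpha[i] + y[i] * tt
    alpha[j] <- alpha[j] - y[j] * tt
    for (v in c(i, j)) {                # snap to the box to keep sets exact
      if (alpha[v] < eps) alpha[v] <- 0
      if (alpha[v] > C[v] - eps) alpha[v] <- C[v]
    }
    G <- G + tt * y * (K[, i] - K[, j])
  }
  m <- -y * G
  free <- alpha > eps & alpha < C - eps
  b <- if (any(free)) {
    mean(m[free])
  } else {
    up <- (y > 0 & alpha < C - eps) | (y < 0 & alpha > eps)
    low <- (y > 0 & alpha > eps) | (y < 0 & alpha < C - eps)
    if (any(up) && any(low)) (max(m[up]) + min(m[low])) / 2 else 0
  }
  list(alpha = alpha, b = b, iterations = it, converged = converged)
}

## One full fit (with optional trimming refit) on a raw matrix; shared by
## training and permutation inference so permutations can reuse the Gram
## matrix.  K must be X X' / scale^2 + offset on ALL subjects.
.fitHyperplane <- function(X, y01, K, params, subset = NULL) {
  n <- length(y01)
  keep <- if (is.null(subset)) seq_len(n) else subset
  y <- ifelse(y01 == 1L, 1, -1)
  ## C_i = box * cost of misclassifying subject i's true class
  cVec <- params@boxConstraint *
    ifelse(y01 == 1L, params@cost[2, 1], params@cost[1, 2])
  fit <- .solveSvmDual(K[keep, keep, drop = FALSE], y[keep], cVec[keep],
                       tol = params@tolerance, maxit = params@maxIterations)
  dropped <- integer(0)
  nDrop <- floor(params@outlierFraction * length(keep))
  if (nDrop > 0L) {
    f <- K[keep, keep, drop = FALSE] %*% (fit$alpha * y[keep]) + fit$b
    slack <- pmax(0, 1 - y[keep] * as.numeric(f))
    ord <- order(-slack, seq_along(slack))
    dropped <- keep[ord[seq_len(nDrop)]]
    keep2 <- setdiff(keep, dropped)
    if (length(unique(y01[keep2])) == 2L && length(keep2) >= 4L) {
      fit <- .solveSvmDual(K[keep2, keep2, drop = FALSE], y[keep2],
                           cVec[keep2], tol = params@tolerance,
                           maxit = params@maxIterations)
      keep <- keep2
    } else {
      dropped <- integer(0)             # trimming would degenerate; keep all
    }
  }
  coefs <- fit$alpha * y[keep]
  w <- as.numeric(crossprod(X[keep, , drop = FALSE], coefs)) /
    params@kernelScale^2
  list(weights = w, bias = fit$b, dropped = dropped,
       iterations = fit$iterations, converged = fit$converged,
       alpha = fit$alpha, keep = keep)
}

.gramMatrix <- function(X, params) {
  tcrossprod(X) / params@kernelScale^2 + params@kernelOffset
}

#' Train the voxel-wise linear classifier
#'
#' Solves the soft-margin dual on the preprocessed feature matrix, trims the
#' configured outlier fraction of largest-slack subjects, refits once, and
#' exports the equivalent primal weight map and bias.  Non-convergence
#' within the iteration cap is reported with a warning and flagged in the
#' provenance, never silently accepted.
#'
#' @param features a [PetFeatureSet-class] with both classes present and at
#'   least 4 subjects.
#' @param params an [SvmParams-class] (default [svmParams()]).
#' @return A [HyperplaneModel-class].
#' @export
trainSvm <- function(features, params = svmParams()) {
  stopifnot(is(features, "PetFeatureSet"))
  X <- featureMatrix(features)
  y01 <- subjectLabels(features)
  if (length(unique(y01)) < 2L) stop("training needs both classes present")
  if (nrow(X) < 4L) stop("training needs at least 4 subjects")
  if (any(!is.finite(X))) stop("non-finite features")
  K <- .gramMatrix(X, params)
  fit <- .fitHyperplane(X, y01, K, params)
  if (!fit$converged)
    warning(sprintf("SVM solver did not converge within %g iterations",
                    params@maxIterations))
  nr <- normalizationRecord(features)
  new("HyperplaneModel",
      weights = fit$weights, bias = fit$bias, params = params,
      voxelIndex = voxelIndex(features),
      gridDim = as.integer(nr$mask$dim),
      voxelSize = as.numeric(nr$voxel_size_mm),
      normalization = nr,
      provenance = list(
        classCounts = as.list(table(y01)),
        trimmedSubjects = subjectIds(features)[fit$dropped],
        iterations = fit$iterations, converged = fit$converged,
        seed = params@seed))
}

#' Score preprocessed subjects under a frozen model
#'
#' The subject score is the inner product of the weight map with the
#' preprocessed image vector, plus the bias; its sign is the predicted
#' class.  The feature set's normalization record must match the model's
#' training record exactly - a mismatch is an error, never a silent rescale.
#'
#' @param model a [HyperplaneModel-class].
#' @param features a [PetFeatureSet-class] preprocessed like the training
#'   data.
#' @return named numeric vector of scores.
#' @export
subjectScores <- function(model, features) {
  stopifnot(is(model, "HyperplaneModel"), is(features, "PetFeatureSet"))
  if (!.sameNormalization(model@normalization,
                          normalizationRecord(features)))
    stop("normalization record mismatch: features were not preprocessed like the training data")
  X <- featureMatrix(features)
  if (ncol(X) != length(model@weights))
    stop(sprintf("voxel count mismatch: model has %d, features have %d",
                 length(model@weights), ncol(X)))
  setNames(as.numeric(X %*% model@weights) + model@bias,
           subjectIds(features))
}

#' Score a bare image vector
#'
#' Low-level scoring of an already-aligned voxel vector; use
#' [subjectScores()] for feature sets so the normalization record is
#' enforced.
#'
#' @param model a [HyperplaneModel-class].
#' @param x numeric vector aligned to the model's voxel index.
#' @return the score, \code{sum(w * x) + b}.
#' @export
subjectScore <- function(model, x) {
  if (length(x) != length(model@weights))
    stop(sprintf("voxel count mismatch: model has %d, vector has %d",
                 length(model@weights), length(x)))
  sum(model@weights * x) + model@bias
}

#' Classify subject scores
#'
#' Label 1 (converter) iff the score is strictly positive; a score of
#' exactly 0 is classified as 0 (stable).
#'
#' @param score numeric vector of finite subject scores.
#' @return integer vector of 0/1 labels.
#' @export
classifyScore <- function(score) {
  if (any(!is.finite(score))) stop("scores must be finite")
  as.integer(score > 0)
}
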