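## Independent oracles and small fixtures, built in code.

## libsvm (e1071) as an independent solver of the same soft-margin problem.
## The kernel offset is immaterial on the feasible set (sum(alpha*y) = 0),
## and kernel scale s is equivalent to feature scaling by 1/s.  libsvm's
## positive decision value corresponds to the first label seen in training;
## the returned scores are aligned so that class 1 scores positive.
oracleSvmScores <- function(X, y01, boxConstraint = 1, kernelScale = 1,
                            tol = 1e-9) {
  fit <- e1071::svm(X / kernelScale, factor(y01, levels = c(0, 1)),
                    kernel = "linear", cost = boxConstraint, scale = FALSE,
                    tolerance = tol)
  w <- t(fit$SV) %*% fit$coefs
  scores <- as.numeric((X / kernelScale) %*% w) - fit$rho
  pred <- predict(fit, X / kernelScale)
  ## align sign: positive score must mean predicted class "1"
  agree <- mean((scores > 0) == (pred == "1"))
  if (agree < 0.5) scores <- -scores
  scores
}

## Brute-force dense 3-D convolution with a truncated Gaussian kernel
## normalized over its full support.  Valid comparison region: voxels at
## least halfWidth away from every face (there the package's per-axis
## renormalization equals global normalization).
denseGaussianConvolution <- function(arr, sigmaVox) {
  hw <- pmax(1L, ceiling(4 * sigmaVox))
  off <- expand.grid(dx = -hw[1]:hw[1], dy = -hw[2]:hw[2], dz = -hw[3]:hw[3])
  kern <- exp(-(off$dx^2 / sigmaVox[1]^2 + off$dy^2 / sigmaVox[2]^2 +
                  off$dz^2 / sigmaVox[3]^2) / 2)
  kern <- kern / sum(kern)
  d <- dim(arr)
  out <- array(NA_real_, d)
  for (i in (hw[1] + 1):(d[1] - hw[1]))
    for (j in (hw[2] + 1):(d[2] - hw[2]))
      for (k in (hw[3] + 1):(d[3] - hw[3]))
        out[i, j, k] <- sum(kern * arr[cbind(i + off$dx, j + off$dy,
                                             k + off$dz)])
  out
}

## Exhaustive pairwise AUC: every (positive, negative) pair, ties half.
aucByPairCounting <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

## Desk-scale simulation settings on a 12x14x12 grid (module unit tests).
tinyRegions <- function(amplitude = 0.3) {
  list(list(center = c(4.5, 5.5, 8.0), radius = 2.0, sign = "hypo",
            amplitude = amplitude),
       list(center = c(6.5, 10.0, 6.5), radius = 1.5, sign = "hyper",
            amplitude = amplitude))
}

tinyConfig <- function(amplitude = 0.3, nPerClass = c(8L, 8L), seed = 1L,
                       noiseSd = 0.1, globalScaleSd = 0.1, ...) {
  simulationConfig(gridShape = c(12L, 14L, 12L), voxelSize = c(4, 4, 4),
                   nPerClass = nPerClass,
                   effectRegions = tinyRegions(amplitude),
                   noiseSd = noiseSd, globalScaleSd = globalScaleSd,
                   seed = seed, ...)
}

## Feature set wrapping a bare n x p matrix (subjects x voxels).
matrixFeatureSet <- function(X, labels, fwhm = 8, target = 50) {
  p <- ncol(X)
  record <- list(fwhm_mm = fwhm, target = target,
                 mask = list(dim = c(p, 1L, 1L), nVoxels = p,
                             checksum = p * 1.5),
                 voxel_size_mm = c(1, 1, 1), order = "smooth-then-scale")
  petFeatureSet(t(X), cbind(i = seq_len(p), j = 1L, k = 1L),
                sprintf("s%02d", seq_len(nrow(X))), labels, record)
}

## Bare hyperplane with chosen weights/bias, for scoring and p-value tests.
toyModel <- function(weights, bias = 0) {
  p <- length(weights)
  new("HyperplaneModel", weights = weights, bias = bias,
      params = svmParams(),
      voxelIndex = cbind(i = seq_len(p), j = 1L, k = 1L),
      gridDim = c(p, 1L, 1L), voxelSize = c(1, 1, 1),
      normalization = list(fwhm_mm = 8, target = 50,
                           mask = list(dim = c(p, 1L, 1L), nVoxels = p,
                                       checksum = p * 1.5),
                           voxel_size_mm = c(1, 1, 1)),
      provenance = list())
}

## Separable two-class Gaussian instance for solver tests.
separableInstance <- function(n, p, gap = 2, seed = 1) {
  set.seed(seed)
  y01 <- rep(c(0L, 1L), c(ceiling(n / 2), floor(n / 2)))
  X <- matrix(rnorm(n * p), n, p) + outer(ifelse(y01 == 1L, gap, -gap),
                                          rep(1, p))
  list(X = X, y01 = y01)
}
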