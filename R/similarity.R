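## Spatial comparison of two voxel pattern maps: Pearson correlation over
## the mask, with a p-value from phase-randomized surrogate maps that
## preserve the first map's spatial autocorrelation (its 3-D Fourier
## amplitude spectrum).

#' Pearson spatial correlation of two maps
#'
#' @param mapA,mapB [BrainVolume-class] objects on a shared grid.
#' @param mask a [BrainMask-class] with at least 3 voxels.
#' @return Pearson r over the mask voxels.
#' @export
spatialCorrelation <- function(mapA, mapB, mask) {
  stopifnot(is(mapA, "BrainVolume"), is(mapB, "BrainVolume"),
            is(mask, "BrainMask"))
  if (!identical(dim(mapA@data), dim(mask@data)) ||
      !identical(dim(mapB@data), dim(mask@data)))
    stop("maps and mask must share one grid")
  a <- mapA@data[mask@data]
  b <- mapB@data[mask@data]
  if (length(a) < 3L) stop("need at least 3 mask voxels")
  if (sd(a) == 0 || sd(b) == 0)
    stop("zero variance inside the mask in at least one map")
  cor(a, b)
}

#' Phase-randomized surrogate of a volume
#'
#' Returns a volume with exactly the same 3-D Fourier amplitude spectrum as
#' the input but with random phases (taken from the FFT of a white-noise
#' field, which guarantees the Hermitian symmetry of a real field).  The
#' surrogate therefore shares the input's spatial autocorrelation function.
#' No mask is applied here; see [autocorrSimilarityTest()].
#'
#' @param vol a [BrainVolume-class].
#' @return a surrogate [BrainVolume-class] (same grid and voxel size).
#' @export
phaseRandomize <- function(vol) {
  stopifnot(is(vol, "BrainVolume"))
  d <- dim(vol@data)
  amp <- Mod(fft(vol@data))
  noise <- array(rnorm(prod(d)), d)
  ph <- Arg(fft(noise))
  surr <- Re(fft(amp * exp(1i * ph), inverse = TRUE)) / prod(d)
  brainVolume(surr, vol@voxelSize, vol@affine)
}

#' Autocorrelation-corrected spatial similarity test
#'
#' Tests whether the spatial correlation between \code{mapA} and \code{mapB}
#' exceeds what maps with \code{mapA}'s smoothness produce by chance:
#' surrogates of \code{mapA} are built by Fourier phase randomization
#' (amplitude spectrum preserved), re-masked, re-matched to \code{mapA}'s
#' in-mask mean and variance, and correlated with \code{mapB}.  The p-value
#' is two-sided on the magnitude, \code{(b + 1) / (n + 1)} with \code{b} the
#' count of surrogates with \code{|r_surr| >= |r_obs|}, so it is always in
#' (0, 1].
#'
#' @param mapA,mapB [BrainVolume-class] maps on a shared grid; surrogates
#'   are generated from \code{mapA}.
#' @param mask a [BrainMask-class].
#' @param nSurrogates number of surrogate maps (>= 19; default 199).
#' @param seed integer RNG seed.
#' @return A [SimilarityResult-class].
#' @export
autocorrSimilarityTest <- function(mapA, mapB, mask, nSurrogates = 199L,
                                   seed = 1L) {
  stopifnot(nSurrogates >= 19L)
  rObs <- spatialCorrelation(mapA, mapB, mask)
  inMask <- mask@data
  aVals <- mapA@data[inMask]
  mu <- mean(aVals); sdA <- sd(aVals)
  b <- mapB@data[inMask]
  set.seed(seed)
  rSurr <- numeric(nSurrogates)
  for (s in seq_len(nSurrogates)) {
    sv <- phaseRandomize(mapA)@data[inMask]
    sdS <- sd(sv)
    if (sdS == 0) stop("degenerate surrogate (zero variance)")
    sv <- (sv - mean(sv)) / sdS * sdA + mu
    rSurr[s] <- cor(sv, b)
  }
  p <- (sum(abs(rSurr) >= abs(rObs)) + 1) / (nSurrogates + 1)
  new("SimilarityResult", r = rObs, p = p,
      nSurrogates = as.integer(nSurrogates), surrogateR = rSurr,
      seed = as.integer(seed))
}
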