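## Synthetic cohort generator: a deterministic ellipsoidal brain phantom with
## planted hypo-/hypermetabolic spherical regions, subject-level lognormal
## global scaling (the nuisance proportional scaling removes) and additive
## in-mask Gaussian noise.

#' Simulation configuration
#'
#' @param gridShape integer(3) grid (default 32 x 40 x 32; left-right,
#'   posterior-anterior, inferior-superior).
#' @param voxelSize numeric(3) voxel size in mm (default 4 mm isotropic).
#' @param nPerClass integer(2): subjects in class 0 (stable) and class 1
#'   (converter).  Defaults to c(20, 23), the size of a typical single-center
#'   conversion cohort.
#' @param effectRegions list of regions, each
#'   \code{list(center=, radius=, sign=, amplitude=)} with center/radius in
#'   voxel units, sign "hypo" or "hyper", amplitude a fraction of template
#'   intensity in [0, 1).  Default: [defaultEffectRegions()].
#' @param noiseSd SD of additive Gaussian noise inside the mask, in template
#'   intensity units (template shell is 1.0).  Default 0.1.
#' @param globalScaleSd log-scale SD of the subject-level multiplicative
#'   global factor (median 1).  Default 0.1.
#' @param smoothingFwhm FWHM (mm) of an optional acquisition-resolution
#'   smoothing applied to the simulated volumes; 0 (default) leaves the noise
#'   i.i.d. and defers all smoothing to preprocessing.
#' @param seed integer RNG seed.
#' @return A validated configuration list of class "SimulationConfig".
#' @export
simulationConfig <- function(gridShape = c(32L, 40L, 32L),
                             voxelSize = c(4, 4, 4),
                             nPerClass = c(20L, 23L),
                             effectRegions = defaultEffectRegions(),
                             noiseSd = 0.1,
                             globalScaleSd = 0.1,
                             smoothingFwhm = 0,
                             seed = 1L) {
  stopifnot(length(gridShape) == 3L, all(gridShape >= 1),
            length(voxelSize) == 3L, all(voxelSize > 0),
            length(nPerClass) == 2L, all(nPerClass >= 1),
            noiseSd >= 0, globalScaleSd >= 0, smoothingFwhm >= 0)
  for (r in effectRegions) {
    if (!all(c("center", "radius", "sign", "amplitude") %in% names(r)))
      stop("each effect region needs center, radius, sign, amplitude")
    if (!r$sign %in% c("hypo", "hyper"))
      stop("effect region sign must be 'hypo' or 'hyper'")
    if (r$amplitude < 0 || r$amplitude >= 1)
      stop("effect amplitudes must lie in [0, 1)")
  }
  structure(list(gridShape = as.integer(gridShape),
                 voxelSize = as.numeric(voxelSize),
                 nPerClass = as.integer(nPerClass),
                 effectRegions = effectRegions,
                 noiseSd = noiseSd, globalScaleSd = globalScaleSd,
                 smoothingFwhm = smoothingFwhm, seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Default planted effect regions
#'
#' A lobar-scale pattern emulating the topography reported for dementia
#' conversion in parkinsonism: bilateral posterior "parietal" and lateral
#' "temporal" hypometabolism, with medial-anterior "cingulate/SMA" and
#' bilateral deep "putamen/insula" relative hypermetabolism.  Coordinates are
#' voxel units on the default 32 x 40 x 32 grid.
#'
#' @param amplitude fractional effect size applied to every region
#'   (default 0.15).
#' @return list of effect regions for [simulationConfig()].
#' @export
defaultEffectRegions <- function(amplitude = 0.15) {
  reg <- function(center, radius, sign)
    list(center = center, radius = radius, sign = sign,
         amplitude = amplitude)
  list(
    reg(c(10.0, 13.5, 19.0), 5.0, "hypo"),   # L parietal
    reg(c(23.0, 13.5, 19.0), 5.0, "hypo"),   # R parietal
    reg(c(9.0, 18.0, 11.5), 4.5, "hypo"),    # L temporal
    reg(c(24.0, 18.0, 11.5), 4.5, "hypo"),   # R temporal
    reg(c(16.5, 27.0, 15.0), 4.0, "hyper"),  # anterior cingulum / SMA
    reg(c(12.5, 24.5, 15.0), 3.0, "hyper"),  # L putamen / insula
    reg(c(20.5, 24.5, 15.0), 3.0, "hyper"))  # R putamen / insula
}

## Normalized ellipsoidal radius^2 of every voxel.
.ellipsoidRho2 <- function(gridShape, semi = NULL) {
  if (is.null(semi)) semi <- 0.46 * gridShape
  ctr <- (gridShape + 1) / 2
  i <- (seq_len(gridShape[1]) - ctr[1]) / semi[1]
  j <- (seq_len(gridShape[2]) - ctr[2]) / semi[2]
  k <- (seq_len(gridShape[3]) - ctr[3]) / semi[3]
  outer(outer(i^2, j^2, `+`), k^2, `+`)
}

#' Deterministic brain phantom
#'
#' A smooth, strictly positive "brain-like" field inside an ellipsoidal mask:
#' intensity rises quadratically from ~1.0 at the shell to 2.5 in deep
#' structures, with a mild anterior-posterior gradient for asymmetry; zero
#' outside the mask.  Purely deterministic in the configuration.
#'
#' @param config a [simulationConfig()].
#' @return \code{list(template = BrainVolume, mask = BrainMask)}.
#' @export
makePhantom <- function(config) {
  gs <- config$gridShape
  if (any(gs < 8L)) stop("degenerate grid: need >= 8 voxels per axis")
  rho2 <- .ellipsoidRho2(gs)
  mask <- rho2 <= 1
  ctr <- (gs + 1) / 2
  yhat <- (seq_len(gs[2]) - ctr[2]) / (0.46 * gs[2])
  grad <- array(rep(rep(yhat, each = gs[1]), gs[3]), gs)
  tpl <- (1 + 1.5 * (1 - rho2)) * (1 + 0.05 * grad)
  tpl[!mask] <- 0
  list(template = brainVolume(tpl, config$voxelSize),
       mask = brainMask(mask, config$voxelSize))
}

#' Signed planted effect field
#'
#' The voxel-wise field E with +amplitude inside "hyper" regions, -amplitude
#' inside "hypo" regions and 0 elsewhere; class-1 subjects receive
#' template * (1 + E).  Errors if a region escapes the mask or if regions of
#' opposite sign overlap.
#'
#' @param config a [simulationConfig()].
#' @param mask the phantom [BrainMask-class].
#' @return 3-D numeric array of the same grid.
#' @export
effectField <- function(config, mask) {
  gs <- config$gridShape
  E <- array(0, gs)
  ctr <- expand.grid(i = seq_len(gs[1]), j = seq_len(gs[2]),
                     k = seq_len(gs[3]))
  for (r in config$effectRegions) {
    d2 <- (ctr$i - r$center[1])^2 + (ctr$j - r$center[2])^2 +
          (ctr$k - r$center[3])^2
    inside <- array(d2 <= r$radius^2, gs)
    if (any(inside & !mask@data))
      stop(sprintf("effect region at (%s) escapes the brain mask",
                   paste(r$center, collapse = ",")))
    amp <- if (r$sign == "hyper") r$amplitude else -r$amplitude
    clash <- inside & (sign(E) == -sign(amp)) & (E != 0)
    if (any(clash))
      stop("effect regions of opposite sign overlap")
    E[inside] <- amp
  }
  E
}

#' Simulate a labeled cohort
#'
#' Subject i of class c receives \code{g_i * (template * (1 + c * E)) + eps_i}
#' (optionally smoothed), where E is the signed effect field, \code{g_i} is
#' lognormal with median 1 and log-SD \code{globalScaleSd}, and \code{eps_i}
#' is i.i.d. Gaussian(0, noiseSd) inside the mask.  Class 0 receives E = 0.
#' Fully reproducible from the configuration seed.
#'
#' @param config a [simulationConfig()].
#' @return A [PetCohort-class]; class-0 subjects precede class-1 subjects.
#' @export
simulateCohort <- function(config) {
  ph <- makePhantom(config)
  E <- effectField(config, ph$mask)
  tplArr <- ph$template@data
  maskArr <- ph$mask@data
  nMask <- sum(maskArr)
  labels <- rep(c(0L, 1L), config$nPerClass)
  n <- length(labels)
  set.seed(config$seed)
  g <- rlnorm(n, meanlog = 0, sdlog = config$globalScaleSd)
  vols <- vector("list", n)
  for (s in seq_len(n)) {
    base <- if (labels[s] == 1L) tplArr * (1 + E) else tplArr
    arr <- g[s] * base
    arr[maskArr] <- arr[maskArr] + rnorm(nMask, sd = config$noiseSd)
    vol <- brainVolume(arr, config$voxelSize)
    if (config$smoothingFwhm > 0)
      vol <- smoothGaussian(vol, config$smoothingFwhm)
    vols[[s]] <- vol
  }
  ids <- sprintf("sub%03d", seq_len(n))
  petCohort(vols, ids, labels, ph$mask,
            provenance = list(config = unclass(config)))
}
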