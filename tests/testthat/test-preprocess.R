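test_that("Gaussian smoothing preserves constants and matches the FWHM/sigma relation", {
  const <- brainVolume(array(3, c(10, 10, 10)), voxelSize = c(2, 2, 2))
  sm <- smoothGaussian(const, 8)
  expect_lt(max(abs(voxelData(sm) - 3)), 1e-6)
  expect_equal(fwhmToSigma(8) / 2, 1.6986, tolerance = 1e-4)
  expect_error(smoothGaussian(const, 0), "positive")
})

test_that("smoothing matches a brute-force dense convolution oracle away from boundaries", {
  set.seed(4)
  d <- c(14L, 15L, 14L)
  arr <- array(rnorm(prod(d)), d)
  vol <- brainVolume(arr, voxelSize = c(2, 2.5, 2))
  fwhm <- 5
  sm <- smoothGaussian(vol, fwhm)
  sig <- fwhmToSigma(fwhm) / voxelSize(vol)
  oracle <- denseGaussianConvolution(arr, sig)
  inner <- !is.na(oracle)
  expect_lt(max(abs(voxelData(sm)[inner] - oracle[inner])), 1e-6)

  ## unit impulse at the center reproduces the sampled separable kernel
  imp <- array(0, c(21L, 21L, 21L)); imp[11, 11, 11] <- 1
  impVol <- brainVolume(imp, voxelSize = c(2, 2, 2))
  smImp <- smoothGaussian(impVol, 8)
  oracleImp <- denseGaussianConvolution(imp, rep(fwhmToSigma(8) / 2, 3))
  ok <- !is.na(oracleImp)
  expect_lt(max(abs(voxelData(smImp)[ok] - oracleImp[ok])), 1e-6)
})

test_that("proportional scaling hits the target mean and is scale invariant", {
  m <- brainMask(array(rep(c(TRUE, FALSE), c(500, 12)), c(8, 8, 8)))
  v <- brainVolume(array(7, c(8, 8, 8)))
  out <- proportionalScale(v, m, target = 50)
  expect_equal(voxelData(out)[voxelData(m)], rep(50, 500))

  set.seed(5)
  x <- brainVolume(array(runif(512, 1, 3), c(8, 8, 8)))
  a <- proportionalScale(x, m)
  b <- proportionalScale(brainVolume(voxelData(x) * 3.7), m)
  expect_equal(voxelData(a), voxelData(b), tolerance = 1e-12)
  expect_equal(mean(voxelData(a)[voxelData(m)]), 50, tolerance = 1e-9)

  half <- proportionalScale(brainVolume(array(2, c(8, 8, 8))), m, target = 1)
  expect_equal(voxelData(half), array(1, c(8, 8, 8)))
  expect_error(proportionalScale(brainVolume(array(0, c(8, 8, 8))), m),
               "nonpositive")
})

test_that("vectorization flattens mask voxels reproducibly, row order = cohort order", {
  cfg <- tinyConfig(nPerClass = c(3L, 3L), seed = 9L)
  coh <- simulateCohort(cfg)
  feats <- vectorizeCohort(coh)
  X <- featureMatrix(feats)
  expect_equal(nrow(X), 6L)
  expect_equal(ncol(X), sum(voxelData(cohortMask(coh))))
  expect_equal(unname(rowMeans(X)), rep(50, 6), tolerance = 1e-6)

  ## identical volumes give identical rows
  cc <- petCohort(rep(list(coh[[1]]), 3), c("a", "b", "c"), c(0, 1, 0),
                  cohortMask(coh))
  Xc <- featureMatrix(vectorizeCohort(cc))
  expect_identical(Xc[1, ], Xc[2, ])
  expect_identical(Xc[1, ], Xc[3, ])

  ## a global factor on one raw subject changes nothing after scaling
  vols <- coh@volumes
  vols[[2]] <- brainVolume(voxelData(vols[[2]]) * 10, voxelSize(vols[[2]]))
  coh10 <- petCohort(vols, subjectIds(coh), subjectLabels(coh),
                     cohortMask(coh))
  expect_equal(featureMatrix(vectorizeCohort(coh10)), X, tolerance = 1e-12)

  ## voxel_index scatter round-trip reconstructs the masked processed volume
  vol1 <- proportionalScale(smoothGaussian(coh[[1]], 8), cohortMask(coh), 50)
  rebuilt <- scatterToVolume(X[1, ], cohortMask(coh))
  msk <- voxelData(cohortMask(coh))
  expect_identical(voxelData(rebuilt)[msk], voxelData(vol1)[msk])
})

test_that("the implemented operation order is smooth-then-scale", {
  ## an impulse at the mask edge loses mass across the boundary when
  ## smoothed, so the two orders provably differ on this input
  cfg <- tinyConfig()
  ph <- makePhantom(cfg)
  edge <- which(voxelData(ph$mask))[1]
  arr <- array(1, dim(voxelData(ph$mask)))
  arr[edge] <- 100
  vol <- brainVolume(arr, voxelSize = cfg$voxelSize)
  coh <- petCohort(list(vol, vol), c("a", "b"), c(0, 1), ph$mask)

  smoothScale <- proportionalScale(smoothGaussian(vol, 8), ph$mask, 50)
  scaleSmooth <- smoothGaussian(proportionalScale(vol, ph$mask, 50), 8)
  expect_gt(max(abs(voxelData(smoothScale) - voxelData(scaleSmooth))), 1e-6)

  X <- featureMatrix(vectorizeCohort(coh, fwhm = 8, target = 50))
  idx <- which(voxelData(ph$mask))
  expect_identical(X[1, ], voxelData(smoothScale)[idx])
})

test_that("grid mismatches and empty cohorts are rejected", {
  cfg <- tinyConfig(nPerClass = c(2L, 2L))
  coh <- simulateCohort(cfg)
  small <- brainMask(array(TRUE, c(4, 4, 4)))
  expect_error(vectorizeCohort(coh, mask = small), "grid")
  empty <- petCohort(list(), character(0), integer(0), cohortMask(coh))
  expect_error(vectorizeCohort(empty), "empty")
})
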