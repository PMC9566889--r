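test_that("a symmetric two-point problem puts the boundary at zero", {
  fs <- matrixFeatureSet(matrix(c(-1, -1, 1, 1), 4, 1), c(0L, 0L, 1L, 1L))
  m <- trainSvm(fs, svmParams(outlierFraction = 0, kernelOffset = 0))
  expect_equal(modelBias(m), 0, tolerance = 1e-8)
  sc <- subjectScores(m, fs)
  expect_identical(classifyScore(sc), c(0L, 0L, 1L, 1L))
})

test_that("solutions match the independent libsvm oracle on random separable instances", {
  set.seed(10)
  for (r in seq_len(12)) {
    inst <- separableInstance(n = sample(8:20, 1), p = sample(2:10, 1),
                              seed = 100 + r)
    C <- runif(1, 0.2, 5)
    ks <- sample(c(1, 2), 1)
    fs <- matrixFeatureSet(inst$X, inst$y01)
    m <- trainSvm(fs, svmParams(outlierFraction = 0, boxConstraint = C,
                                kernelScale = ks, kernelOffset = 0.1,
                                tolerance = 1e-10))
    mine <- unname(subjectScores(m, fs))
    oracle <- oracleSvmScores(inst$X, inst$y01, boxConstraint = C,
                              kernelScale = ks)
    expect_lt(max(abs(mine - oracle)) / max(abs(oracle)), 1e-5)
  }
})

test_that("the trained solution satisfies the KKT conditions", {
  inst <- separableInstance(12, 4, seed = 3)
  prm <- svmParams(outlierFraction = 0, kernelOffset = 0.3,
                   boxConstraint = 2, tolerance = 1e-10)
  fs <- matrixFeatureSet(inst$X, inst$y01)
  m <- trainSvm(fs, prm)
  K <- petstratify:::.gramMatrix(inst$X, prm)
  fit <- petstratify:::.fitHyperplane(inst$X, inst$y01, K, prm)
  y <- ifelse(inst$y01 == 1L, 1, -1)
  f <- as.numeric(K %*% (fit$alpha * y)) + fit$bias
  marg <- y * f
  free <- fit$alpha > 1e-8 & fit$alpha < 2 - 1e-8
  expect_lt(max(abs(marg[free] - 1)), 1e-6)          # on the margin
  expect_true(all(marg[fit$alpha < 1e-8] >= 1 - 1e-6))   # outside
  expect_true(all(marg[fit$alpha > 2 - 1e-8] <= 1 + 1e-6)) # inside/violating
  expect_lt(abs(sum(fit$alpha * y)), 1e-8)           # equality constraint
})

test_that("swapping class labels negates weights, bias and scores", {
  inst <- separableInstance(14, 5, seed = 7)
  prm <- svmParams(outlierFraction = 0, tolerance = 1e-10)
  fs <- matrixFeatureSet(inst$X, inst$y01)
  fsSwap <- matrixFeatureSet(inst$X, 1L - inst$y01)
  m1 <- trainSvm(fs, prm)
  m2 <- trainSvm(fsSwap, prm)
  expect_equal(modelWeights(m2), -modelWeights(m1), tolerance = 1e-6)
  expect_equal(modelBias(m2), -modelBias(m1), tolerance = 1e-6)
})

test_that("training is deterministic: identical inputs give bit-identical weights", {
  cfg <- tinyConfig(seed = 12L)
  feats <- vectorizeCohort(simulateCohort(cfg))
  m1 <- trainSvm(feats)
  m2 <- trainSvm(feats)
  expect_identical(modelWeights(m1), modelWeights(m2))
  expect_identical(modelBias(m1), modelBias(m2))
})

test_that("feature scaling by c with box 1/c^2 leaves decision labels unchanged", {
  inst <- separableInstance(16, 6, gap = 1, seed = 9)
  cc <- 3
  m1 <- trainSvm(matrixFeatureSet(inst$X, inst$y01),
                 svmParams(outlierFraction = 0, boxConstraint = 1,
                           tolerance = 1e-10))
  m2 <- trainSvm(matrixFeatureSet(inst$X * cc, inst$y01),
                 svmParams(outlierFraction = 0, boxConstraint = 1 / cc^2,
                           tolerance = 1e-10))
  s1 <- unname(subjectScores(m1, matrixFeatureSet(inst$X, inst$y01)))
  s2 <- unname(subjectScores(m2, matrixFeatureSet(inst$X * cc, inst$y01)))
  expect_identical(classifyScore(s1), classifyScore(s2))
  expect_equal(s2, s1, tolerance = 1e-6)   # scores are scale-invariant too
})

test_that("subject scores are the affine form w.x + b", {
  m0 <- toyModel(rep(0, 5), bias = 0.7)
  expect_equal(subjectScore(m0, rnorm(5)), 0.7)
  mh <- toyModel(c(0, 0, 2, 0, 0), bias = 0)
  expect_equal(subjectScore(mh, c(9, 9, 3, 9, 9)), 6)
  m <- toyModel(rnorm(5), bias = 0.3)
  x1 <- rnorm(5); x2 <- rnorm(5)
  expect_equal(subjectScore(m, x1 + x2),
               subjectScore(m, x1) + subjectScore(m, x2) - 0.3)
  expect_error(subjectScore(m, rnorm(4)), "voxel count mismatch")
})

test_that("classification is sign-based with ties to stable", {
  expect_identical(classifyScore(c(0.001, -5, 0)), c(1L, 0L, 0L))
  expect_error(classifyScore(c(1, NA)), "finite")
})

test_that("degenerate training inputs are rejected", {
  X <- matrix(rnorm(20), 5, 4)
  expect_error(trainSvm(matrixFeatureSet(X, rep(1L, 5))), "both classes")
  expect_error(trainSvm(matrixFeatureSet(X[1:3, ], c(0L, 1L, 0L))),
               "at least 4")
  Xb <- X; Xb[2, 2] <- NA
  expect_error(trainSvm(matrixFeatureSet(Xb, c(0L, 1L, 0L, 1L, 0L))),
               "non-finite")
})

test_that("outlier trimming drops the configured fraction of largest-slack points", {
  inst <- separableInstance(20, 4, gap = 1.5, seed = 21)
  ## plant one flagrant outlier: a class-0 point deep in class-1 territory
  inst$X[1, ] <- 4
  fs <- matrixFeatureSet(inst$X, inst$y01)
  m <- trainSvm(fs, svmParams(outlierFraction = 0.05, tolerance = 1e-10))
  expect_identical(m@provenance$trimmedSubjects, "s01")
  ## with trimming off the model keeps everyone
  m0 <- trainSvm(fs, svmParams(outlierFraction = 0, tolerance = 1e-10))
  expect_length(m0@provenance$trimmedSubjects, 0)
})
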