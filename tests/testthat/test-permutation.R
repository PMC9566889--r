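test_that("the forced identity permutation reproduces the true model, giving p = 1", {
  cfg <- tinyConfig(seed = 41L)
  feats <- vectorizeCohort(simulateCohort(cfg))
  n <- length(subjectLabels(feats))
  pn <- permutationNull(feats, nPermutations = 1L,
                        permutations = matrix(seq_len(n), 1))
  expect_true(all(pn$exceedance == 1L))
  pm <- voxelPValues(pn)
  expect_true(all(pValues(pm) == 1))
  expect_true(all(patternSigns(pm) == 0L))
  ## strict-inequality variant: a tie is not an exceedance
  pnStrict <- permutationNull(feats, nPermutations = 1L, ties = "gt",
                              permutations = matrix(seq_len(n), 1))
  expect_true(all(pnStrict$exceedance == 0L))
})

test_that("permutation runs are reproducible from the seed", {
  cfg <- tinyConfig(seed = 42L)
  feats <- vectorizeCohort(simulateCohort(cfg))
  a <- permutationNull(feats, nPermutations = 15L, seed = 7L)
  b <- permutationNull(feats, nPermutations = 15L, seed = 7L)
  expect_identical(a$exceedance, b$exceedance)
})

test_that("p-values are direct exceedance proportions with correct edge cases", {
  m <- toyModel(c(1, -2, 3))
  pm <- voxelPValuesFromCounts(m, c(0L, 10L, 5L), 10L)
  expect_equal(pValues(pm), c(0, 1, 0.5))
  ## true |w| = 2 against null samples {1, 3, 1.5, 2.5}: 2 of 4 exceed
  expect_equal(sum(abs(c(1, 3, 1.5, 2.5)) >= 2) / 4, 0.5)
  pm2 <- voxelPValuesFromCounts(toyModel(c(2, 2, 2)), c(2L, 2L, 2L), 4L)
  expect_equal(pValues(pm2), rep(0.5, 3))
  ## all-zero true weights: every null |w| >= 0, so p = 1 everywhere
  pmz <- voxelPValuesFromCounts(toyModel(rep(0, 4)), rep(4L, 4), 4L)
  expect_true(all(pValues(pmz) == 1))
  ## smoothing estimator
  pms <- voxelPValuesFromCounts(m, c(0L, 10L, 5L), 10L, smoothing = TRUE)
  expect_equal(pValues(pms), c(1, 11, 6) / 11)
  expect_error(voxelPValuesFromCounts(m, c(0L, 11L, 5L), 10L), "exceeds")
})

test_that("signed significance carries the sign of the true weight", {
  m <- toyModel(c(1.5, -2, 0.3, -0.1))
  pm <- voxelPValuesFromCounts(m, c(0L, 0L, 9L, 0L), 10L, alpha = 0.05)
  expect_identical(patternSigns(pm), c(1L, -1L, 0L, -1L))
  vol <- thresholdPattern(pm, m)
  expect_equal(as.numeric(voxelData(vol)), c(1.5, -2, 0, -0.1))
  ## alpha = 1 keeps everything with p < 1; tiny alpha empties the pattern
  pmAll <- voxelPValuesFromCounts(m, c(0L, 0L, 9L, 0L), 10L)
  expect_equal(as.numeric(voxelData(thresholdPattern(pmAll, m, alpha = 1))),
               c(1.5, -2, 0.3, -0.1))
  ## as alpha -> 0+ only voxels with exceedance count 0 (p = 0) survive;
  ## once every count is >= 1 the pattern is empty
  tinyA <- thresholdPattern(pmAll, m, alpha = 1e-12)
  expect_identical(as.numeric(voxelData(tinyA)) != 0, pValues(pmAll) == 0)
  pmPos <- voxelPValuesFromCounts(m, c(1L, 1L, 9L, 2L), 10L)
  expect_true(all(voxelData(thresholdPattern(pmPos, m, alpha = 1e-12)) == 0))
  expect_error(thresholdPattern(pm, m, alpha = 0), "alpha")
})

test_that("a planted effect is recovered with matching signs at desk scale", {
  cfg <- tinyConfig(amplitude = 0.4, nPerClass = c(10L, 10L), seed = 43L)
  feats <- vectorizeCohort(simulateCohort(cfg))
  pn <- permutationNull(feats, nPermutations = 60L, seed = 44L)
  pm <- voxelPValues(pn, alpha = 0.05)
  ph <- makePhantom(cfg)
  E <- effectField(cfg, ph$mask)[voxelIndex(feats)]
  pat <- patternSigns(pm)
  expect_gt(diceOverlap(E != 0, pat != 0), 0.4)
  both <- E != 0 & pat != 0
  expect_gt(mean(sign(E[both]) == pat[both]), 0.95)
})

test_that("p-values are invariant to a global positive rescaling of all raw images", {
  cfg <- tinyConfig(seed = 45L, nPerClass = c(6L, 6L))
  coh <- simulateCohort(cfg)
  scaled <- petCohort(lapply(coh@volumes, function(v)
    brainVolume(voxelData(v) * 17, voxelSize(v))),
    subjectIds(coh), subjectLabels(coh), cohortMask(coh))
  f1 <- vectorizeCohort(coh)
  f2 <- vectorizeCohort(scaled)
  a <- permutationNull(f1, nPermutations = 10L, seed = 3L)
  b <- permutationNull(f2, nPermutations = 10L, seed = 3L)
  expect_identical(a$exceedance, b$exceedance)
})

test_that("Dice overlap follows its definition", {
  expect_equal(diceOverlap(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE)),
               2 / 3)
  expect_equal(diceOverlap(rep(TRUE, 4), rep(TRUE, 4)), 1)
  expect_equal(diceOverlap(c(TRUE, FALSE), c(FALSE, TRUE)), 0)
})
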