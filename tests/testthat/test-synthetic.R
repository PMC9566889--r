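test_that("the phantom is deterministic, positive inside a proper mask", {
  cfg <- tinyConfig()
  ph1 <- makePhantom(cfg)
  ph2 <- makePhantom(cfg)
  expect_identical(voxelData(ph1$template), voxelData(ph2$template))
  nvox <- sum(voxelData(ph1$mask))
  expect_gt(nvox, 0)
  expect_lt(nvox, prod(dim(voxelData(ph1$mask))))
  expect_gt(min(voxelData(ph1$template)[voxelData(ph1$mask)]), 0)
  expect_true(all(voxelData(ph1$template)[!voxelData(ph1$mask)] == 0))
  expect_error(makePhantom(simulationConfig(gridShape = c(6L, 14L, 12L))),
               "degenerate grid")
})

test_that("simulation is seed-reproducible and degenerates to the template", {
  cfg <- tinyConfig(seed = 3L)
  c1 <- simulateCohort(cfg)
  c2 <- simulateCohort(cfg)
  expect_identical(voxelData(c1[[5]]), voxelData(c2[[5]]))

  quiet <- simulationConfig(gridShape = c(12L, 14L, 12L),
                            nPerClass = c(2L, 2L), effectRegions = list(),
                            noiseSd = 0, globalScaleSd = 0)
  coh <- simulateCohort(quiet)
  tpl <- makePhantom(quiet)$template
  for (s in seq_len(length(coh)))
    expect_identical(voxelData(coh[[s]]), voxelData(tpl))
})

test_that("effect regions must stay inside the mask, carry valid amplitudes, and not clash", {
  esc <- simulationConfig(gridShape = c(12L, 14L, 12L), effectRegions = list(
    list(center = c(2, 2, 2), radius = 2, sign = "hypo", amplitude = 0.2)))
  expect_error(simulateCohort(esc), "escapes the brain mask")
  expect_error(simulationConfig(effectRegions = list(
    list(center = c(16, 20, 16), radius = 2, sign = "hypo",
         amplitude = -0.1))), "amplitudes")
  expect_error(simulationConfig(effectRegions = list(
    list(center = c(16, 20, 16), radius = 2, sign = "down",
         amplitude = 0.1))), "sign")
  clash <- simulationConfig(gridShape = c(12L, 14L, 12L), effectRegions = list(
    list(center = c(6.5, 7.5, 6.5), radius = 2, sign = "hypo",
         amplitude = 0.2),
    list(center = c(7.5, 7.5, 6.5), radius = 2, sign = "hyper",
         amplitude = 0.2)))
  ph <- makePhantom(clash)
  expect_error(effectField(clash, ph$mask), "opposite sign overlap")
})

test_that("the effect field carries the planted signs at the planted amplitude", {
  cfg <- tinyConfig(amplitude = 0.25)
  ph <- makePhantom(cfg)
  E <- effectField(cfg, ph$mask)
  expect_setequal(unique(as.numeric(E)), c(-0.25, 0, 0.25))
  ## converters get template * (1 + E): check one noiseless subject
  cfg0 <- tinyConfig(amplitude = 0.25, noiseSd = 0, globalScaleSd = 0)
  coh <- simulateCohort(cfg0)
  conv <- voxelData(coh[[which(subjectLabels(coh) == 1L)[1]]])
  expect_equal(conv, voxelData(ph$template) * (1 + E))
})

test_that("with zero planted amplitude a per-voxel two-sample test rejects at the nominal rate", {
  ## 200 null cohorts; one fixed in-mask voxel; Welch t at alpha = 0.05.
  ## 95% Monte-Carlo band for 200 Bernoulli(0.05) trials: [0.02, 0.08].
  cfg <- tinyConfig(amplitude = 0, nPerClass = c(6L, 6L))
  ph <- makePhantom(cfg)
  vox <- which(voxelData(ph$mask))[100]
  rej <- vapply(seq_len(200), function(s) {
    coh <- simulateCohort(tinyConfig(amplitude = 0, nPerClass = c(6L, 6L),
                                     seed = 1000L + s))
    vals <- vapply(seq_len(length(coh)),
                   function(i) voxelData(coh[[i]])[vox], numeric(1))
    stats::t.test(vals[subjectLabels(coh) == 1L],
                  vals[subjectLabels(coh) == 0L])$p.value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.08)
})
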