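test_that("simulation is deterministic given the seed and extends stably", {
  spec <- cohortSpec(counts = c(HC = 3, MCI = 2), montage = tinyMontage(),
                     duration = 18, seed = 41)
  sim1 <- simulateCohort(spec)
  sim2 <- simulateCohort(spec)
  expect_identical(recordingSamples(sim1$recordings$HC01$run1),
                   recordingSamples(sim2$recordings$HC01$run1))
  expect_identical(recordingSamples(sim1$recordings$MCI02$run2),
                   recordingSamples(sim2$recordings$MCI02$run2))

  pv1 <- simulatePowerVectors(spec, nEpochs = 9)
  pv2 <- simulatePowerVectors(spec, nEpochs = 9)
  expect_identical(pv1$series, pv2$series)

  # participant substreams: growing the cohort leaves earlier participants
  # untouched
  bigger <- cohortSpec(counts = c(HC = 5, MCI = 2), montage = tinyMontage(),
                       duration = 18, seed = 41)
  pv3 <- simulatePowerVectors(bigger, nEpochs = 9)
  expect_identical(pv3$series$HC01, pv1$series$HC01)
  expect_identical(pv3$series$HC03, pv1$series$HC03)
})

test_that("generated powers are strictly positive and correctly shaped", {
  spec <- cohortSpec(counts = c(HC = 2, AD = 2), seed = 42)
  pv <- simulatePowerVectors(spec, nEpochs = 36)
  s <- pv$series$HC01$frontal
  expect_equal(dim(s$run1), c(36L, 7L))
  expect_equal(dim(s$run2), c(36L, 7L))
  expect_length(pv$series$AD01, 6L)
  expect_true(all(unlist(lapply(pv$series, lapply, lapply, min)) > 0))
  expect_equal(unname(pv$groups["AD02"]), "AD")
  expect_error(simulatePowerVectors(spec, nEpochs = 0), ">= 1")
})

test_that("degenerate spec (no jitter, no perturbation) gives identical runs", {
  pert <- perturbMatrix("HC", fill = 0)
  spec <- cohortSpec(counts = c(HC = 2), subjectLogSd = 0, jitterLogSd = 0,
                     perturbLogSd = pert, seed = 43)
  pv <- simulatePowerVectors(spec, nEpochs = 5)
  s <- pv$series$HC01$parietal
  expect_equal(s$run1, s$run2)
  expect_equal(s$run1[1, ], s$run1[5, ])       # no epoch-to-epoch jitter
  expect_equal(unname(s$run1[1, ]), c(8, 8, 10, 10, 8, 6, 4))
})

test_that("group-dependent perturbation lowers the perturbed group's BRS", {
  spec <- strongEffectSpec(seed = 44, n = 20)
  pv <- simulatePowerVectors(spec, nEpochs = 36)
  brs <- brsFromPowerVectors(pv$series, pv$groups)
  rawMeans <- tapply(brs$raw, brs$group, mean)
  expect_gt(rawMeans["HC"], rawMeans["MCI"])
  # standardized MCI mean negative (parameter-recovery property)
  expect_lt(mean(brs$std[brs$group == "MCI"]), 0)
})

test_that("under a zero-effect spec the groups are statistically similar", {
  pvals <- vapply(1:20, function(s) {
    spec <- nullEffectSpec(seed = 500 + s, n = 8)
    pv <- simulatePowerVectors(spec, nEpochs = 12)
    brs <- brsFromPowerVectors(pv$series, pv$groups)
    frontal <- brs[brs$region == "frontal", ]
    ranksumTest(frontal$raw[frontal$group == "HC"],
                frontal$raw[frontal$group == "MCI"])$p.value
  }, numeric(1))
  # exact-test discreteness makes the per-seed level at most 0.05; allow
  # the 99.7% binomial band around it for 20 replicates
  expect_lte(sum(pvals <= 0.05), 4L)
})

test_that("signal-level and power-level generators agree on group ordering", {
  hits <- 0L
  for (s in 1:10) {
    pert <- perturbMatrix(c("HC", "MCI"), fill = 0.05,
                          MCI = c(low_beta = 0.8, high_beta = 0.8,
                                  gamma = 0.8))
    spec <- cohortSpec(counts = c(HC = 6, MCI = 6), montage = tinyMontage(),
                       perturbLogSd = pert, duration = 18, seed = 600 + s)
    pv <- simulatePowerVectors(spec, nEpochs = 6)
    brsP <- brsFromPowerVectors(pv$series, pv$groups)
    gapP <- with(brsP, mean(raw[group == "HC"]) - mean(raw[group == "MCI"]))

    sig <- simulateCohort(spec)
    cohort <- lapply(sig$recordings, function(p) lapply(p, function(rec)
      segmentEpochs(bandpassFilter(rec, 0.5, 50), 6, 0.6)))
    brsS <- computeBrsFeatures(cohort, sig$groups, montage = tinyMontage())
    gapS <- with(brsS, mean(raw[group == "HC"]) - mean(raw[group == "MCI"]))
    hits <- hits + as.integer(gapP > 0 && gapS > 0)
  }
  expect_gte(hits, 8L)   # same rank order, allowing Monte-Carlo slack
})

test_that("signal-level recordings carry the requested band structure", {
  pert <- perturbMatrix("HC", fill = 0)
  spec <- cohortSpec(counts = c(HC = 1), montage = tinyMontage(),
                     subjectLogSd = 0, jitterLogSd = 0, perturbLogSd = pert,
                     duration = 18, seed = 45)
  sim <- simulateCohort(spec)
  rec <- sim$recordings$HC01$run1
  expect_s4_class(rec, "EEGRecording")
  expect_equal(ncol(recordingSamples(rec)), 9000L)
  x <- recordingSamples(rec)[1, ]
  b <- defaultBands()
  est <- vapply(seq_len(7), function(i)
    epochBandPower(x[1:3000], 500, c(b$low[i], b$high[i])), numeric(1))
  # band powers follow the alpha-dominant profile within periodogram noise
  expect_equal(est, c(8, 8, 10, 10, 8, 6, 4), tolerance = 0.5)
  expect_error(simulateCohort(cohortSpec(counts = c(HC = 1), duration = 3)),
               "shorter than one epoch")
})

test_that("cohorts round-trip through the array format on disk", {
  spec <- cohortSpec(counts = c(HC = 1, AD = 1), montage = tinyMontage(),
                     duration = 18, seed = 46)
  sim <- simulateCohort(spec)
  dir <- withr::local_tempdir()
  manifest <- writeCohort(sim, dir)
  m <- readManifest(file.path(dir, "manifest.csv"))
  expect_equal(m$participant, c("HC01", "AD01"))
  back <- readRecording(m$run2[2], montage = tinyMontage())
  expect_identical(recordingSamples(back),
                   recordingSamples(sim$recordings$AD01$run2))
  expect_equal(back@group, "AD")
})
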