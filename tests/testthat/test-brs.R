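test_that("between-run similarity matches hand-computed examples", {
  expect_equal(as.numeric(betweenRunSimilarity(rbind(c(0, 0)), rbind(c(3, 4)))),
               1 / 5)
  S <- betweenRunSimilarity(rbind(c(0, 0), c(1, 0)), rbind(c(3, 4)))
  expect_equal(as.numeric(S), (1 / 5 + 1 / sqrt(20)) / 2, tolerance = 1e-12)
  expect_equal(attr(S, "n"), 2L)
  expect_equal(attr(S, "m"), 1L)
  # zero-distance degenerate case is floored, not infinite
  Sdeg <- betweenRunSimilarity(rbind(c(1, 1)), rbind(c(1, 1)))
  expect_true(is.finite(Sdeg))
  expect_equal(as.numeric(Sdeg), 1e12)
  expect_error(betweenRunSimilarity(rbind(c(1, 2)), rbind(c(1, 2, 3))),
               "dimension mismatch")
})

test_that("vectorized similarity equals the double-loop oracle to 12 digits", {
  set.seed(31)
  for (k in 1:100) {
    n <- sample(1:40, 1); m <- sample(1:40, 1); d <- sample(1:7, 1)
    P1 <- matrix(rexp(n * d, rate = 0.2), nrow = n)
    P2 <- matrix(rexp(m * d, rate = 0.2), nrow = m)
    expect_equal(as.numeric(betweenRunSimilarity(P1, P2)),
                 brsDoubleLoop(P1, P2), tolerance = 1e-12)
  }
})

test_that("similarity is symmetric under run swap and homogeneous of degree -1", {
  set.seed(32)
  for (k in 1:20) {
    P1 <- matrix(rexp(5 * 7), nrow = 5)
    P2 <- matrix(rexp(8 * 7), nrow = 8)
    expect_equal(as.numeric(betweenRunSimilarity(P1, P2)),
                 as.numeric(betweenRunSimilarity(P2, P1)), tolerance = 1e-12)
    c0 <- runif(1, 0.1, 10)
    expect_equal(as.numeric(betweenRunSimilarity(c0 * P1, c0 * P2)),
                 as.numeric(betweenRunSimilarity(P1, P2)) / c0,
                 tolerance = 1e-10)
  }
})

test_that("similarity strictly decreases with between-run displacement", {
  set.seed(33)
  P1 <- matrix(rexp(10 * 7), nrow = 10)
  offsets <- c(0.5, 1, 2, 4)
  vals <- vapply(offsets, function(o) {
    P2 <- P1; P2[, 3] <- P2[, 3] + o
    as.numeric(betweenRunSimilarity(P1, P2))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[1], as.numeric(betweenRunSimilarity(P1, P1)))
})

test_that("standardization reproduces hand examples and the HC identity", {
  v <- c(a = 0.1, b = 0.2, c = 0.3, x = 0.2, y = 0.35)
  s <- standardizeBrs(v, hcIds = c("a", "b", "c"))
  expect_equal(unname(s["x"]), 0)
  expect_equal(unname(s["y"]), 1.5)
  # HC mean 0 / sample sd 1 exactly, for arbitrary cohorts
  set.seed(34)
  v2 <- stats::setNames(rexp(30), paste0("p", 1:30))
  hc <- paste0("p", 1:11)
  s2 <- standardizeBrs(v2, hc)
  expect_equal(mean(s2[hc]), 0, tolerance = 1e-12)
  expect_equal(sd(s2[hc]), 1, tolerance = 1e-12)
  # population-sd variant rescales by sqrt((n-1)/n)
  s3 <- standardizeBrs(v2, hc, sdType = "population")
  expect_equal(unname(s3[hc][1] / s2[hc][1]), sqrt(11 / 10), tolerance = 1e-12)
})

test_that("standardization guards against degenerate benchmarks", {
  expect_error(standardizeBrs(c(a = 1, b = 2), hcIds = "a"), "at least 2")
  expect_error(standardizeBrs(c(a = 1, b = 1, c = 2), hcIds = c("a", "b")),
               "zero spread")
  expect_error(standardizeBrs(unname(c(1, 2, 3)), hcIds = "a"), "named")
  # fold-train mode restricts the benchmark to training HCs
  v <- c(a = 1, b = 2, c = 9, d = 5)
  s <- standardizeBrs(v, hcIds = c("a", "b", "c"), mode = "fold-train",
                      trainIds = c("a", "b", "d"))
  expect_equal(unname(s["a"]), (1 - 1.5) / sd(c(1, 2)))
  expect_error(standardizeBrs(v, hcIds = c("a", "b"), mode = "fold-train"),
               "trainIds")
})

test_that("cohort-level BRS yields one row per participant and region", {
  spec <- cohortSpec(counts = c(HC = 20, MCI = 14, AD = 10), seed = 35)
  sim <- simulatePowerVectors(spec, nEpochs = 12)
  brs <- brsFromPowerVectors(sim$series, sim$groups)
  expect_equal(nrow(brs), 44 * 6)
  expect_equal(as.vector(table(brs$participant)), rep(6L, 44))
  expect_true(all(brs$raw > 0))
  expect_true(all(is.finite(brs$std)))
  expect_equal(brs$n[1], 12L)
  # per-region HC standardization identity
  for (r in unique(brs$region)) {
    hcv <- brs$std[brs$region == r & brs$group == "HC"]
    expect_equal(mean(hcv), 0, tolerance = 1e-10)
    expect_equal(sd(hcv), 1, tolerance = 1e-10)
  }
  fm <- brsFeatureMatrix(brs)
  expect_equal(dim(fm$X), c(44L, 6L))
  expect_equal(colnames(fm$X), regionNames(defaultMontage()))
  expect_equal(unname(fm$y[1]), "HC")
})

test_that("cohort BRS from epoch arrays validates run completeness", {
  set.seed(36)
  mkEp <- function(run) {
    mats <- lapply(1:3, function(i) matrix(rnorm(4 * 500), nrow = 4))
    epochArrayFrom(mats, 250, c("F1", "F2", "B1", "B2"), run = run)
  }
  cohort <- list(h1 = list(run1 = mkEp(1L), run2 = mkEp(2L)),
                 h2 = list(run1 = mkEp(1L), run2 = mkEp(2L)),
                 m1 = list(run1 = mkEp(1L), run2 = mkEp(2L)))
  groups <- c(h1 = "HC", h2 = "HC", m1 = "MCI")
  brs <- computeBrsFeatures(cohort, groups, montage = tinyMontage())
  expect_equal(nrow(brs), 3L * 2L)
  expect_equal(brs$band_set[1], "all")

  broken <- cohort
  broken$m1$run2 <- NULL
  expect_error(computeBrsFeatures(broken, groups, montage = tinyMontage()),
               "m1")
  # a single HC cannot define the benchmark spread
  expect_error(computeBrsFeatures(cohort[c("h1", "m1")],
                                  groups, montage = tinyMontage()),
               "at least 2")
})

test_that("per-band similarity uses a one-dimensional power vector", {
  set.seed(37)
  mkEp <- function(run) {
    mats <- lapply(1:4, function(i) matrix(rnorm(4 * 500), nrow = 4))
    epochArrayFrom(mats, 250, c("F1", "F2", "B1", "B2"), run = run)
  }
  cohort <- list(p1 = list(run1 = mkEp(1L), run2 = mkEp(2L)),
                 p2 = list(run1 = mkEp(1L), run2 = mkEp(2L)),
                 p3 = list(run1 = mkEp(1L), run2 = mkEp(2L)))
  groups <- c(p1 = "HC", p2 = "HC", p3 = "MCI")
  brs <- computeBrsFeatures(cohort, groups, montage = tinyMontage(),
                            bandNames = "low_beta")
  expect_equal(unique(brs$band_set), "low_beta")
  expect_equal(nrow(brs), 6L)
})
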