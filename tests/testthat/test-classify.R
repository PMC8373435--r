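test_that("LDA decision boundary passes through the class-mean midpoint", {
  set.seed(61)
  X <- rbind(matrix(rnorm(20, mean = 2), ncol = 2),
             matrix(rnorm(20, mean = -1), ncol = 2))
  y <- rep(c("P", "N"), each = 10)
  m <- ldaFit(X, y, positive = "P", priors = "equal")
  mid <- (m$muP + m$muN) / 2
  expect_equal(ldaDecide(m, mid), 0, tolerance = 1e-10)
  # equal priors and equal penalties: no log-odds offset for any data
  expect_equal(m$logTerm, 0)
})

test_that("one-dimensional LDA reproduces the closed-form score 2x", {
  # class means +1/-1, pooled unit variance
  c1 <- 1 / sqrt(2)
  X <- matrix(c(1 + c1, 1 - c1, -1 + c1, -1 - c1), ncol = 1)
  y <- c("P", "P", "N", "N")
  m <- ldaFit(X, y, positive = "P", priors = "equal")
  for (x in c(-1, 0, 0.5, 2))
    expect_equal(ldaDecide(m, x), 2 * x, tolerance = 1e-10)
})

test_that("LDA is invariant to common invertible affine transforms", {
  set.seed(62)
  X <- rbind(matrix(rnorm(60, 1), ncol = 3), matrix(rnorm(60, -1), ncol = 3))
  y <- rep(c("P", "N"), each = 20)
  Xtest <- matrix(rnorm(30), ncol = 3)
  A <- matrix(c(2, 0.5, 0, -1, 3, 0.2, 0.1, 0, 1.5), 3, 3)
  shift <- c(5, -2, 7)
  m1 <- ldaFit(X, y, positive = "P")
  m2 <- ldaFit(sweep(X %*% A, 2, shift, "+"), y, positive = "P")
  s1 <- ldaDecide(m1, Xtest)
  s2 <- ldaDecide(m2, sweep(Xtest %*% A, 2, shift, "+"))
  expect_equal(s1, s2, tolerance = 1e-8)
})

test_that("LDA agrees with an independent reference implementation", {
  set.seed(63)
  X <- rbind(matrix(rnorm(80, 1.2), ncol = 4), matrix(rnorm(60, 0), ncol = 4))
  y <- c(rep("P", 20), rep("N", 15))
  m <- ldaFit(X, y, positive = "P")                 # proportional priors
  ref <- MASS::lda(X, grouping = y)
  Xnew <- matrix(rnorm(200), ncol = 4)
  ours <- ifelse(ldaDecide(m, Xnew) > 0, "P", "N")
  theirs <- as.character(predict(ref, Xnew)$class)
  expect_equal(ours, theirs)
})

test_that("LDA guards degenerate inputs", {
  base <- c(1, 2, 3, 4, 8, 9, 10, 11)
  X <- cbind(base, 2 * base)                        # exactly collinear
  y <- rep(c("P", "N"), each = 4)
  expect_error(ldaFit(X, y, positive = "P", shrinkage = "none"),
               "shrinkage")
  m <- ldaFit(X, y, positive = "P")
  expect_gt(m$lambda, 0)                            # auto-shrinkage engaged
  expect_error(ldaFit(matrix(1:4, ncol = 1), rep("P", 4)), "two classes")
})

test_that("SVM separates a separable pair and satisfies kernel identities", {
  X <- rbind(c(-1, 0), c(1, 0), c(-1, 0.2), c(1, 0.2))
  y <- c("N", "P", "N", "P")
  m <- svmFit(X, y, C = 100, gamma = 1, positive = "P")
  s <- svmDecide(m, rbind(c(-1, 0), c(1, 0)))
  expect_lt(s[1], 0)
  expect_gt(s[2], 0)
  expect_error(svmFit(rbind(c(NA, 1), c(0, 1), c(1, 0), c(2, 0)),
                      y, C = 1, gamma = 1), "non-finite")
  expect_error(svmFit(X, y, C = -1, gamma = 1), "positive")
})

test_that("SVM decision values match a quadratic-programming oracle", {
  set.seed(64)
  for (rep in 1:3) {
    X <- rbind(matrix(rnorm(20, mean = 2, sd = 0.5), ncol = 2),
               matrix(rnorm(20, mean = -2, sd = 0.5), ncol = 2))
    ylab <- rep(c("P", "N"), each = 10)
    ynum <- ifelse(ylab == "P", 1, -1)
    C <- 100; gamma <- 0.5
    m <- svmFit(X, ylab, C = C, gamma = gamma, positive = "P")
    oracle <- svmQpOracle(X, ynum, C, gamma)
    Xnew <- rbind(X, matrix(rnorm(12), ncol = 2))
    expect_equal(svmDecide(m, Xnew), oracle(Xnew), tolerance = 1e-4)
  }
})

test_that("LOPO-CV accuracy has 1/N granularity and finds clean structure", {
  set.seed(65)
  for (s in 1:10) {
    X <- rbind(matrix(rnorm(20, mean = 5), ncol = 2),
               matrix(rnorm(20, mean = -5), ncol = 2))
    y <- rep(c("P", "N"), each = 10)
    cv <- lopoCv(X, y, classifier = "lda", positive = "P")
    expect_equal(cv$accuracy, 1.0)
  }
  # granularity: accuracy * N is an integer
  X <- matrix(rnorm(40), ncol = 2)
  y <- rep(c("P", "N"), each = 10)
  cv <- lopoCv(X, y, classifier = "svm", C = 1, gamma = 0.5, positive = "P")
  expect_equal(cv$accuracy * 20, round(cv$accuracy * 20))
  expect_equal(nrow(cv$folds), 20L)
  expect_error(lopoCv(X[1:2, ], y[1:2]), "at least 3")
  expect_error(lopoCv(rbind(X, 0), c(y, "Q")), "two classes")
})

test_that("LOPO-CV is at chance under label permutation", {
  set.seed(66)
  X <- matrix(rnorm(80), ncol = 2)
  y0 <- rep(c("P", "N"), each = 20)
  accs <- vapply(1:100, function(i)
    lopoCv(X, sample(y0), classifier = "lda", positive = "P",
           priors = "equal")$accuracy,
    numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("fold-train standardization uses only training healthy controls", {
  set.seed(67)
  Xraw <- matrix(rexp(20 * 3), ncol = 3,
                 dimnames = list(paste0("p", 1:20), c("a", "b", "c")))
  tf <- brsFoldStandardizer(hcIds = paste0("p", 1:10))
  out <- tf(Xraw[2:20, ], Xraw[1, , drop = FALSE])
  hcTrain <- intersect(paste0("p", 1:10), rownames(out$train))
  expect_equal(unname(colMeans(out$train[hcTrain, ])), rep(0, 3),
               tolerance = 1e-12)
  expect_equal(unname(apply(out$train[hcTrain, ], 2, sd)), rep(1, 3),
               tolerance = 1e-12)
  expect_error(brsFoldStandardizer(c("p1"))(Xraw[2:20, ], Xraw[1, , drop = FALSE]),
               "fewer than 2")
})

test_that("parameter grids have the documented cardinality and ordering", {
  g <- defaultParamGrid()
  expect_equal(nrow(g), 900L)                   # 30 x 30 odd exponents
  expect_equal(sort(unique(log2(g$C))), seq(-29, 29, by = 2))
  g31 <- defaultParamGrid(exponents = seq(-30, 30, by = 2))
  expect_equal(nrow(g31), 961L)                 # 31 x 31 alternative
  expect_equal(nrow(smallParamGrid()), 9L)
  expect_true(all(g$C > 0 & g$gamma > 0))
})

test_that("grid search returns the argmax with smallest-C tie-breaking", {
  set.seed(68)
  X <- rbind(matrix(rnorm(20, 4), ncol = 2), matrix(rnorm(20, -4), ncol = 2))
  y <- rep(c("P", "N"), each = 10)
  single <- gridSearchSvm(X, y, grid = data.frame(C = 2, gamma = 0.5),
                          positive = "P")
  expect_equal(single$C, 2)
  expect_equal(single$gamma, 0.5)
  expect_equal(single$accuracy,
               lopoCv(X, y, "svm", C = 2, gamma = 0.5,
                      positive = "P")$accuracy)
  # widely separated data: several grid points reach accuracy 1; the
  # smallest C then smallest gamma must win
  gs <- gridSearchSvm(X, y, grid = data.frame(C = c(1, 1, 4, 4),
                                              gamma = c(0.02, 0.1, 0.02, 0.1)),
                      positive = "P")
  expect_equal(gs$accuracy, 1.0)
  expect_equal(gs$C, 1)
  expect_equal(gs$gamma, 0.02)
  expect_error(gridSearchSvm(X, y, grid = data.frame()), "empty")
})

test_that("SFS ranks a planted informative feature first", {
  set.seed(69)
  n <- 40
  y <- rep(c("P", "N"), each = n / 2)
  X <- matrix(rnorm(n * 6), ncol = 6,
              dimnames = list(NULL, paste0("F", 1:6)))
  X[, 3] <- ifelse(y == "P", 2, -2) + rnorm(n, sd = 0.3)
  tr <- sfsSelect(X, y, classifier = "lda", positive = "P")
  expect_equal(tr$chain[1], "F3")
  expect_equal(tr$bestAccuracy, 1.0)
  expect_equal(tr$bestSubset, "F3")
  # the chain is a permutation of all candidates
  expect_setequal(tr$chain, paste0("F", 1:6))
  # best-subset accuracy dominates the single-feature step
  expect_gte(tr$bestAccuracy, tr$stepAccuracy[1])

  # exhaustive-subset oracle agrees on the optimum accuracy
  allSubsets <- unlist(lapply(1:6, function(k)
    utils::combn(paste0("F", 1:6), k, simplify = FALSE)), recursive = FALSE)
  oracleBest <- max(vapply(allSubsets, function(ss)
    lopoCv(X[, ss, drop = FALSE], y, "lda", positive = "P")$accuracy,
    numeric(1)))
  expect_equal(tr$bestAccuracy, oracleBest)
})

test_that("SFS with a single candidate trivially selects it", {
  set.seed(70)
  X <- matrix(rnorm(20), ncol = 1, dimnames = list(NULL, "only"))
  y <- rep(c("P", "N"), each = 10)
  tr <- sfsSelect(X, y, classifier = "lda", positive = "P")
  expect_equal(tr$chain, "only")
  expect_equal(tr$bestSubset, "only")
  expect_length(tr$stepAccuracy, 1L)
})

test_that("joint SFS + grid search reports the chosen SVM parameters", {
  set.seed(71)
  n <- 24
  y <- rep(c("P", "N"), each = n / 2)
  X <- matrix(rnorm(n * 3), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  X[, 2] <- ifelse(y == "P", 1.5, -1.5) + rnorm(n, sd = 0.5)
  tr <- sfsSelect(X, y, classifier = "svm",
                  grid = data.frame(C = c(1, 8), gamma = c(0.25, 0.25)),
                  positive = "P")
  expect_s3_class(tr, "SFSTrace")
  expect_true(tr$C %in% c(1, 8))
  expect_equal(tr$gamma, 0.25)
  expect_setequal(tr$chain, c("a", "b", "c"))
  expect_equal(tr$chain[1], "b")
  expect_gte(tr$bestAccuracy, max(tr$stepAccuracy))
})
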