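#' @include brs.R
NULL

twoClassSplit <- function(y, positive) {
  classes <- unique(as.character(y))
  if (length(classes) != 2L)
    stop(sprintf("exactly two classes are required, got: %s",
                 paste(classes, collapse = ", ")))
  if (is.null(positive)) positive <- classes[1]
  if (!positive %in% classes)
    stop(sprintf("positive class '%s' not present", positive))
  list(positive = positive, negative = setdiff(classes, positive))
}

shrinkCovariance <- function(Sigma, maxCond = 1e8) {
  target <- mean(diag(Sigma))
  if (!is.finite(target) || target <= 0)
    stop("degenerate covariance: zero total variance")
  for (lambda in c(0, 10^seq(-6, -0.5, by = 0.5), 0.9)) {
    S <- (1 - lambda) * Sigma + lambda * target * diag(nrow(Sigma))
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 0 && max(ev) / min(ev) <= maxCond)
      return(list(Sigma = S, lambda = lambda))
  }
  list(Sigma = (1 - 0.9) * Sigma + 0.9 * target * diag(nrow(Sigma)),
       lambda = 0.9)
}

#' Fit a two-class linear discriminant classifier
#'
#' Linear discriminant with pooled within-class covariance and the signed
#' decision score
#' \deqn{D(x) = (\mu_P-\mu_N)^t \Sigma^{-1} x
#'   - \tfrac12 (\mu_P-\mu_N)^t \Sigma^{-1} (\mu_P+\mu_N)
#'   - \ln\frac{C_P \pi_N}{C_N \pi_P},}
#' positive score meaning the positive class.  With equal class penalties
#' (the default) the log term reduces to \eqn{\ln(\pi_N/\pi_P)}.  If the
#' pooled covariance is ill-conditioned (condition number above 1e8) and
#' \code{shrinkage = "auto"}, a scalar shrinkage toward the identity is
#' applied (smallest intensity restoring the condition bound);
#' \code{shrinkage = "none"} errors instead.
#'
#' @param X numeric feature matrix, one row per participant.
#' @param y class labels (two classes).
#' @param positive label of the positive class (default: first class in
#'   \code{y}).
#' @param priors \code{"proportions"} (training frequencies, default) or
#'   \code{"equal"}.
#' @param penaltyP,penaltyN class penalty weights \eqn{C_P, C_N} (default
#'   both 1).
#' @param shrinkage \code{"auto"}, \code{"none"}, or a numeric intensity in
#'   [0, 1].
#' @return an \code{ldaModel} list (weights, means, covariance, log term).
#' @seealso [ldaDecide()]
#' @export
ldaFit <- function(X, y, positive = NULL, priors = c("proportions", "equal"),
                   penaltyP = 1, penaltyN = 1, shrinkage = "auto") {
  priors <- match.arg(priors)
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("non-finite feature values")
  cls <- twoClassSplit(y, positive)
  isP <- as.character(y) == cls$positive
  if (sum(isP) < 1L || sum(!isP) < 1L) stop("both classes must be present")
  XP <- X[isP, , drop = FALSE]; XN <- X[!isP, , drop = FALSE]
  muP <- colMeans(XP); muN <- colMeans(XN)
  nP <- nrow(XP); nN <- nrow(XN)
  pool <- function(A) if (nrow(A) > 1L) stats::cov(A) * (nrow(A) - 1L) else
    matrix(0, ncol(A), ncol(A))
  Sigma <- (pool(XP) + pool(XN)) / max(nP + nN - 2L, 1L)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  lambda <- 0
  illCond <- min(ev) <= 0 || max(ev) / min(ev) > 1e8
  if (illCond) {
    if (identical(shrinkage, "none"))
      stop("pooled covariance is singular or ill-conditioned; use shrinkage")
    if (identical(shrinkage, "auto")) {
      sh <- shrinkCovariance(Sigma)
      Sigma <- sh$Sigma; lambda <- sh$lambda
    }
  }
  if (is.numeric(shrinkage)) {
    lambda <- shrinkage
    Sigma <- (1 - lambda) * Sigma + lambda * mean(diag(Sigma)) * diag(ncol(X))
  }
  piP <- if (priors == "equal") 0.5 else nP / (nP + nN)
  piN <- 1 - piP
  w <- tryCatch(solve(Sigma, muP - muN), error = function(e)
    stop("pooled covariance is singular even after shrinkage; ",
         "more training data or stronger shrinkage is required"))
  structure(list(w = w, muP = muP, muN = muN, Sigma = Sigma,
                 lambda = lambda,
                 logTerm = log((penaltyP * piN) / (penaltyN * piP)),
                 positive = cls$positive, negative = cls$negative),
            class = "ldaModel")
}

#' Signed LDA decision scores
#'
#' @param model an \code{ldaModel} from [ldaFit()].
#' @param X feature matrix (or single feature vector).
#' @return numeric scores; positive means the positive class.
#' @export
ldaDecide <- function(model, X) {
  stopifnot(inherits(model, "ldaModel"))
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  as.numeric(X %*% model$w) -
    0.5 * sum(model$w * (model$muP + model$muN)) - model$logTerm
}

#' Fit a soft-margin RBF-kernel support vector machine
#'
#' Thin wrapper around the libsvm C-classification solver with the radial
#' basis kernel \eqn{K(x_i, x) = \exp(-\gamma \|x_i - x\|^2)}; the decision
#' function is the usual dual form \eqn{\sum_{SV} \alpha_i y_i K(x_i, x) +
#' b} with the bias fixed by the Kuhn-Tucker conditions.  Features are not
#' rescaled.
#'
#' @param X numeric feature matrix.
#' @param y class labels (two classes).
#' @param C penalty weight (> 0).
#' @param gamma RBF kernel parameter (> 0).
#' @param positive label of the positive class (default: first class).
#' @param tolerance solver termination tolerance (default 1e-6, tight
#'   enough that decision values match an exact dual solution to ~1e-5).
#' @return an \code{svmModel} list wrapping the fitted solver.
#' @seealso [svmDecide()]
#' @export
svmFit <- function(X, y, C = 1, gamma = 1, positive = NULL,
                   tolerance = 1e-6) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("non-finite feature values")
  if (C <= 0 || gamma <= 0) stop("C and gamma must be positive")
  cls <- twoClassSplit(y, positive)
  yf <- factor(as.character(y), levels = c(cls$positive, cls$negative))
  fit <- e1071::svm(x = X, y = yf, type = "C-classification",
                    kernel = "radial", gamma = gamma, cost = C,
                    scale = FALSE, tolerance = tolerance)
  # libsvm orders decision values by order of label appearance; determine
  # the sign convention once from the reported level pair
  lev <- colnames(attr(
    stats::predict(fit, X[1, , drop = FALSE], decision.values = TRUE),
    "decision.values"))
  flip <- !identical(lev, paste(cls$positive, cls$negative, sep = "/"))
  structure(list(fit = fit, positive = cls$positive,
                 negative = cls$negative, flip = flip,
                 C = C, gamma = gamma),
            class = "svmModel")
}

#' Signed SVM decision scores
#'
#' @param model an \code{svmModel} from [svmFit()].
#' @param X feature matrix (or single feature vector).
#' @return numeric scores; positive means the positive class.
#' @export
svmDecide <- function(model, X) {
  stopifnot(inherits(model, "svmModel"))
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  dv <- attr(stats::predict(model$fit, X, decision.values = TRUE),
             "decision.values")
  s <- as.numeric(dv[, 1])
  if (model$flip) -s else s
}

#' Leave-one-participant-out cross-validation
#'
#' One fold per participant: the classifier is trained on all other
#' participants and predicts the held-out one; accuracy is the number of
#' correctly classified participants divided by the total (so one
#' misclassification in a 50-participant task moves the error rate by
#' exactly 2 percentage points).
#'
#' @param X feature matrix, one row per participant; rownames are
#'   participant ids (generated if absent).
#' @param y class labels (two classes, each with >= 2 members).
#' @param classifier \code{"lda"} or \code{"svm"}.
#' @param C,gamma SVM parameters (ignored for LDA).
#' @param positive positive-class label (default: first class in \code{y}).
#' @param transform optional per-fold preprocessing
#'   \code{function(Xtrain, Xtest)} returning \code{list(train, test)};
#'   used e.g. to re-standardize BRS features from training healthy
#'   controls only ([brsFoldStandardizer()]).
#' @param ... passed to the classifier fit.
#' @return list with \code{folds} (data frame: participant, truth,
#'   predicted, score) and \code{accuracy}.
#' @export
lopoCv <- function(X, y, classifier = c("lda", "svm"), C = 1, gamma = 1,
                   positive = NULL, transform = NULL, ...) {
  classifier <- match.arg(classifier)
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- paste0("P", seq_len(nrow(X)))
  y <- stats::setNames(as.character(y), rownames(X))
  N <- nrow(X)
  if (N < 3L) stop("LOPO-CV needs at least 3 participants")
  cls <- twoClassSplit(y, positive)
  if (min(table(y)) < 2L) stop("both classes need at least 2 members")
  truth <- character(N); pred <- character(N); score <- numeric(N)
  for (i in seq_len(N)) {
    tr <- setdiff(seq_len(N), i)
    ytr <- y[tr]
    if (length(unique(ytr)) < 2L)
      stop("a fold's training set contains a single class")
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[i, , drop = FALSE]
    if (!is.null(transform)) {
      tf <- transform(Xtr, Xte)
      Xtr <- tf$train; Xte <- tf$test
    }
    model <- if (classifier == "lda")
      ldaFit(Xtr, ytr, positive = cls$positive, ...)
    else
      svmFit(Xtr, ytr, C = C, gamma = gamma, positive = cls$positive, ...)
    s <- if (classifier == "lda") ldaDecide(model, Xte) else
      svmDecide(model, Xte)
    truth[i] <- y[i]
    pred[i] <- if (s > 0) cls$positive else cls$negative
    score[i] <- s
  }
  folds <- data.frame(participant = rownames(X), truth = truth,
                      predicted = pred, score = score,
                      stringsAsFactors = FALSE)
  list(folds = folds, accuracy = mean(truth == pred))
}

#' Per-fold BRS re-standardization from training healthy controls
#'
#' Returns a \code{transform} for [lopoCv()] that standardizes every
#' feature column against the healthy controls present in the fold's
#' training set only (the leakage-safe alternative to whole-cohort
#' standardization).  Input features must be raw similarities with
#' participant ids as rownames.
#'
#' @param hcIds healthy-control participant ids.
#' @param sdType see [standardizeBrs()].
#' @return a \code{function(Xtrain, Xtest)} for [lopoCv()].
#' @export
brsFoldStandardizer <- function(hcIds, sdType = "sample") {
  function(Xtrain, Xtest) {
    hc <- intersect(hcIds, rownames(Xtrain))
    if (length(hc) < 2L)
      stop("fewer than 2 healthy controls in the training fold")
    mu <- colMeans(Xtrain[hc, , drop = FALSE])
    s <- apply(Xtrain[hc, , drop = FALSE], 2, stats::sd)
    if (sdType == "population")
      s <- s * sqrt((length(hc) - 1) / length(hc))
    if (any(!is.finite(s)) || any(s == 0))
      stop("zero spread among training healthy controls")
    list(train = sweep(sweep(Xtrain, 2, mu), 2, s, "/"),
         test = sweep(sweep(Xtest, 2, mu), 2, s, "/"))
  }
}

#' SVM hyperparameter grids
#'
#' \code{defaultParamGrid()} is the exhaustive powers-of-two grid with odd
#' exponents \eqn{\{2^{-29}, 2^{-27}, \ldots, 2^{29}\}} for both C and
#' gamma (30 values each, 900 pairs); \code{exponents} overrides the
#' exponent set (e.g. \code{seq(-30, 30, 2)} for a 31 x 31 grid).
#' \code{smallParamGrid()} is a coarse 3 x 3 grid for desk-scale runs.
#'
#' @param exponents exponent set for both parameters.
#' @return data frame with columns \code{C} and \code{gamma}, ordered by C
#'   then gamma (the tie-break order of the grid search).
#' @export
defaultParamGrid <- function(exponents = seq(-29, 29, by = 2)) {
  g <- expand.grid(gamma = 2^sort(exponents), C = 2^sort(exponents))
  data.frame(C = g$C, gamma = g$gamma)
}

#' @rdname defaultParamGrid
#' @export
smallParamGrid <- function() {
  g <- expand.grid(gamma = 2^c(-5, -1, 3), C = 2^c(-3, 1, 5))
  data.frame(C = g$C, gamma = g$gamma)
}

#' Exhaustive SVM grid search under LOPO-CV
#'
#' Evaluates every (C, gamma) pair with [lopoCv()] and returns the argmax
#' accuracy; ties are broken toward the smallest C, then the smallest
#' gamma.
#'
#' @param X,y,positive,transform as in [lopoCv()].
#' @param grid data frame with columns \code{C}, \code{gamma}.
#' @return list with \code{C}, \code{gamma}, \code{accuracy} and the
#'   per-point accuracies (\code{grid}).
#' @export
gridSearchSvm <- function(X, y, grid = defaultParamGrid(), positive = NULL,
                          transform = NULL) {
  if (nrow(grid) < 1L) stop("empty parameter grid")
  ord <- order(grid$C, grid$gamma)
  grid <- grid[ord, , drop = FALSE]
  acc <- numeric(nrow(grid))
  best <- 1L
  for (k in seq_len(nrow(grid))) {
    acc[k] <- lopoCv(X, y, classifier = "svm", C = grid$C[k],
                     gamma = grid$gamma[k], positive = positive,
                     transform = transform)$accuracy
    if (acc[k] > acc[best]) best <- k
  }
  list(C = grid$C[best], gamma = grid$gamma[best], accuracy = acc[best],
       grid = cbind(grid, accuracy = acc))
}

sfsChain <- function(X, y, classifier, C, gamma, positive, transform) {
  features <- colnames(X)
  chain <- character(0)
  stepAcc <- numeric(0)
  remaining <- features
  while (length(remaining) > 0L) {
    accs <- vapply(remaining, function(f) {
      lopoCv(X[, c(chain, f), drop = FALSE], y, classifier = classifier,
             C = C, gamma = gamma, positive = positive,
             transform = transform)$accuracy
    }, numeric(1))
    pick <- remaining[which.max(accs)]   # first max: montage-order tie-break
    chain <- c(chain, pick)
    stepAcc <- c(stepAcc, max(accs))
    remaining <- setdiff(remaining, pick)
  }
  list(chain = chain, stepAccuracy = stepAcc)
}

#' Sequential forward selection of BRS features under LOPO-CV
#'
#' Greedy wrapper selection: first the single feature with the highest
#' LOPO-CV accuracy, then the best pair extending it, then the best triple,
#' until all features are ranked.  The best subset is the chain prefix with
#' the maximum accuracy.  For the SVM the selection and the grid search are
#' carried out together: a full SFS chain is grown for every grid point and
#' the global argmax over (grid point, chain prefix) is returned.  Ties are
#' broken toward earlier features (montage region order), smaller C, then
#' smaller gamma.
#'
#' @param X feature matrix (columns = candidate features, e.g. the six
#'   regional similarities); column order defines the tie-break order.
#' @param y,positive,transform as in [lopoCv()].
#' @param classifier \code{"lda"} or \code{"svm"}.
#' @param grid SVM parameter grid (default [smallParamGrid()]); ignored for
#'   LDA.
#' @return an \code{SFSTrace} list: \code{chain} (feature ranking),
#'   \code{stepAccuracy}, \code{bestSize}, \code{bestSubset},
#'   \code{bestAccuracy}, and for SVM the chosen \code{C} and \code{gamma}.
#' @export
sfsSelect <- function(X, y, classifier = c("lda", "svm"),
                      grid = smallParamGrid(), positive = NULL,
                      transform = NULL) {
  classifier <- match.arg(classifier)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("F", seq_len(ncol(X)))
  if (ncol(X) < 1L) stop("at least one candidate feature is required")
  if (classifier == "lda") {
    res <- sfsChain(X, y, "lda", 1, 1, positive, transform)
    best <- which.max(res$stepAccuracy)
    out <- list(chain = res$chain, stepAccuracy = res$stepAccuracy,
                bestSize = best, bestSubset = res$chain[seq_len(best)],
                bestAccuracy = res$stepAccuracy[best],
                classifier = "lda", C = NA_real_, gamma = NA_real_)
  } else {
    ord <- order(grid$C, grid$gamma)
    grid <- grid[ord, , drop = FALSE]
    out <- NULL
    for (k in seq_len(nrow(grid))) {
      res <- sfsChain(X, y, "svm", grid$C[k], grid$gamma[k], positive,
                      transform)
      best <- which.max(res$stepAccuracy)
      cand <- list(chain = res$chain, stepAccuracy = res$stepAccuracy,
                   bestSize = best, bestSubset = res$chain[seq_len(best)],
                   bestAccuracy = res$stepAccuracy[best],
                   classifier = "svm", C = grid$C[k], gamma = grid$gamma[k])
      if (is.null(out) || cand$bestAccuracy > out$bestAccuracy)
        out <- cand
    }
  }
  structure(out, class = "SFSTrace")
}

#' @export
print.SFSTrace <- function(x, ...) {
  cat(sprintf("SFSTrace (%s): chain %s\n", x$classifier,
              paste(x$chain, collapse = " > ")))
  cat(sprintf("  step accuracies: %s\n",
              paste(sprintf("%.3f", x$stepAccuracy), collapse = " ")))
  cat(sprintf("  best subset (%d): %s, accuracy %.3f\n", x$bestSize,
              paste(x$bestSubset, collapse = ", "), x$bestAccuracy))
  if (x$classifier == "svm")
    cat(sprintf("  C = 2^%g, gamma = 2^%g\n", log2(x$C), log2(x$gamma)))
  invisible(x)
}
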