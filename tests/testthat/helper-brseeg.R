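# Shared fixtures for the brseeg test suite.  Everything is generated in
# code; no data files.

rmsOf <- function(x) sqrt(mean(x^2))

# Single-channel recording holding a pure sinusoid.
sineRecording <- function(freq, rate = 500, duration = 30, amplitude = 1,
                          channel = "A1") {
  t <- seq_len(round(duration * rate)) / rate
  eegRecording(matrix(amplitude * sin(2 * pi * freq * t), nrow = 1),
               rate = rate, channels = channel)
}

# Two-region, four-electrode montage for fast signal-level tests.
tinyMontage <- function() {
  new("ScalpMontage", regions = list(front = c("F1", "F2"),
                                     back = c("B1", "B2")))
}

# Group -> band perturbation matrix builder.
perturbMatrix <- function(groups, bands = defaultBands()$name, fill = 0.1,
                          ...) {
  p <- matrix(fill, nrow = length(groups), ncol = length(bands),
              dimnames = list(groups, bands))
  edits <- list(...)
  for (g in names(edits)) p[g, names(edits[[g]])] <- edits[[g]]
  p
}

# The acceptance-design strong-effect two-group spec: HC barely perturbed,
# MCI strongly perturbed in the beta/gamma bands.
strongEffectSpec <- function(seed, n = 20) {
  pert <- perturbMatrix(c("HC", "MCI"), fill = 0.05,
                        MCI = c(low_beta = 0.8, high_beta = 0.8, gamma = 0.8))
  cohortSpec(counts = c(HC = n, MCI = n), perturbLogSd = pert, seed = seed)
}

# Zero-effect (null) two-group spec: no run-2 perturbation for anyone.
nullEffectSpec <- function(seed, n = 20) {
  pert <- perturbMatrix(c("HC", "MCI"), fill = 0)
  cohortSpec(counts = c(HC = n, MCI = n), perturbLogSd = pert, seed = seed)
}

# Brute-force BRS oracle: naive double loop over epoch pairs.
brsDoubleLoop <- function(P1, P2, floor = 1e-12) {
  total <- 0
  for (i in seq_len(nrow(P1))) {
    for (j in seq_len(nrow(P2))) {
      d <- sqrt(sum((P2[j, ] - P1[i, ])^2))
      total <- total + 1 / max(d, floor)
    }
  }
  total / (nrow(P1) * nrow(P2))
}

# Brute-force epoch count: enumerate valid start indices.
epochCountEnumerated <- function(total, len, step) {
  starts <- seq(0L, max(total - len, 0L), by = step)
  sum(starts + len <= total & total >= len)
}

# Independent dual-QP oracle for the soft-margin RBF SVM (kernlab::ipop):
# solves max sum(alpha) - alpha' Q alpha / 2 s.t. 0 <= alpha <= C,
# y'alpha = 0, then fixes the bias from the free support vectors.
svmQpOracle <- function(X, y, C, gamma) {
  n <- nrow(X)
  K <- exp(-gamma * as.matrix(stats::dist(X))^2)
  Q <- (y %o% y) * K
  sol <- kernlab::ipop(c = matrix(rep(-1, n)), H = Q,
                       A = matrix(y, nrow = 1), b = 0,
                       l = matrix(rep(0, n)), u = matrix(rep(C, n)),
                       r = 0, sigf = 9, maxiter = 80)
  alpha <- kernlab::primal(sol)
  free <- which(alpha > 1e-6 * C & alpha < C * (1 - 1e-6))
  if (length(free) == 0L) free <- which(alpha > 1e-6 * C)
  b <- mean(vapply(free, function(i)
    y[i] - sum(alpha * y * K[, i]), numeric(1)))
  function(Xnew) {
    D2 <- outer(rowSums(Xnew^2), rowSums(X^2), "+") - 2 * tcrossprod(Xnew, X)
    as.numeric(exp(-gamma * pmax(D2, 0)) %*% (alpha * y) + b)
  }
}

# EpochArray built directly from a list of epoch matrices (channels x L).
epochArrayFrom <- function(epochMats, rate, channels,
                           overlap = 0, participant = "T1", run = 1L) {
  L <- ncol(epochMats[[1]])
  data <- array(0, dim = c(length(epochMats), length(channels), L))
  for (i in seq_along(epochMats)) data[i, , ] <- epochMats[[i]]
  new("EpochArray", participant = participant, run = run, data = data,
      rate = rate, epochS = L / rate, overlap = overlap,
      kept = seq_along(epochMats), channels = channels)
}
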