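#' @include bandpower.R
NULL

#' Single-run spectral-power feature vector
#'
#' For every electrode of a region: the mean over epochs of the band power
#' (run-1 epochs only in the comparison design).  The frontal region with
#' theta therefore gives a 7-dimensional feature vector.
#'
#' @param ep an [EpochArray-class] (run 1).
#' @param montage a [ScalpMontage-class].
#' @param region region name.
#' @param band band name from \code{bands}, e.g. \code{"theta"}.
#' @param bands band scheme (default [defaultBands()]).
#' @return named numeric vector, one mean power per region electrode.
#' @export
singleRunSpectralPower <- function(ep, montage, region, band,
                                   bands = defaultBands()) {
  bands <- bandSubset(bands, band)
  bp <- computeBandPowers(ep, bands)
  electrodes <- regionElectrodes(montage, region)
  missing <- setdiff(electrodes, dimnames(bp@values)[[2]])
  if (length(missing) > 0L)
    stop(sprintf("electrode(s) missing: %s", paste(missing, collapse = ", ")))
  vals <- bp@values[, electrodes, 1, drop = FALSE]
  stats::setNames(colMeans(matrix(vals, nrow = dim(vals)[1])), electrodes)
}

#' Katz's fractal dimension of a waveform
#'
#' Treats the series as a planar curve with unit abscissa spacing:
#' total length \eqn{L = \sum_k \sqrt{1 + (x_{k+1}-x_k)^2}}, maximal
#' excursion from the first point \eqn{d = \max_k \sqrt{k^2 +
#' (x_k-x_0)^2}}, and with \eqn{n = N - 1} steps,
#' \deqn{KFD = \log_{10}(n) / (\log_{10}(n) + \log_{10}(d/L)).}
#' Any affine series gives exactly 1 (d = L); a constant series (d = 0) is
#' defined as 1 (a flat line).
#'
#' @param x numeric series of length >= 3.
#' @return the dimension estimate (>= 1 for typical waveforms).
#' @examples
#' katzFD(c(0, 1, 0, 1, 0))  # 4/3
#' @export
katzFD <- function(x) {
  N <- length(x)
  if (N < 3) stop("series must have at least 3 samples")
  dx <- diff(x)
  L <- sum(sqrt(1 + dx^2))
  k <- seq_len(N - 1)
  d <- max(sqrt(k^2 + (x[-1] - x[1])^2))
  if (d == 0) return(1.0)
  n <- N - 1
  log10(n) / (log10(n) + log10(d / L))
}

#' Per-electrode mean Katz fractal dimension of a region
#'
#' KFD of every epoch of every region electrode, averaged over epochs.
#'
#' @inheritParams singleRunSpectralPower
#' @return named numeric vector, one mean KFD per region electrode.
#' @export
katzFeatureVector <- function(ep, montage, region) {
  stopifnot(is(ep, "EpochArray"))
  electrodes <- regionElectrodes(montage, region)
  missing <- setdiff(electrodes, ep@channels)
  if (length(missing) > 0L)
    stop(sprintf("electrode(s) missing: %s", paste(missing, collapse = ", ")))
  n <- nEpochs(ep)
  out <- vapply(electrodes, function(el) {
    j <- match(el, ep@channels)
    mean(vapply(seq_len(n), function(i) katzFD(ep@data[i, j, ]), numeric(1)))
  }, numeric(1))
  stats::setNames(out, electrodes)
}

# Welch auto-/cross-spectra over tapered sub-windows; returns averaged
# spectra per frequency bin.
welchCrossSpectra <- function(x, y, rate, windowS, overlap) {
  L <- round(windowS * rate)
  step <- max(1L, round(L * (1 - overlap)))
  n <- length(x)
  nWin <- epochCount(n, L, step)
  if (nWin < 2L)
    stop("fewer than 2 coherence sub-windows; single-segment coherence is identically 1")
  w <- hannTaper(L)
  nyq <- floor(L / 2)
  Sxx <- Syy <- numeric(nyq + 1)
  Sxy <- complex(real = numeric(nyq + 1))
  for (k in seq_len(nWin)) {
    idx <- ((k - 1L) * step + 1L):((k - 1L) * step + L)
    xs <- w * (x[idx] - mean(x[idx]))
    ys <- w * (y[idx] - mean(y[idx]))
    X <- stats::fft(xs)[1:(nyq + 1)]
    Y <- stats::fft(ys)[1:(nyq + 1)]
    Sxx <- Sxx + Mod(X)^2
    Syy <- Syy + Mod(Y)^2
    Sxy <- Sxy + Conj(X) * Y
  }
  list(freq = (0:nyq) * rate / L, Sxx = Sxx, Syy = Syy, Sxy = Sxy)
}

#' Band-averaged magnitude-squared coherence of two signals
#'
#' Welch-type estimate: Hann-tapered sub-windows (default 1 s, 50% overlap)
#' within the epoch give averaged auto- and cross-spectra; the
#' magnitude-squared coherence \eqn{|S_{xy}|^2 / (S_{xx} S_{yy})} is then
#' averaged over the frequency bins in \code{[low, high)}.  Requires at
#' least 2 sub-windows (single-segment coherence is identically 1 and is
#' refused).
#'
#' @param x,y equal-length numeric signals.
#' @param rate sampling rate in Hz.
#' @param band numeric \code{c(low, high)} in Hz.
#' @param windowS sub-window length in seconds (default 1).
#' @param overlap sub-window overlap fraction (default 0.5).
#' @return coherence in [0, 1].
#' @export
bandCoherence <- function(x, y, rate, band, windowS = 1, overlap = 0.5) {
  if (length(x) != length(y)) stop("signals must have equal length")
  if (length(band) != 2 || band[1] >= band[2])
    stop("band must be c(low, high) with low < high")
  sp <- welchCrossSpectra(x, y, rate, windowS, overlap)
  sel <- sp$freq >= band[1] & sp$freq < band[2]
  if (!any(sel)) stop("band contains no frequency bins at this window length")
  denom <- sp$Sxx[sel] * sp$Syy[sel]
  msc <- ifelse(denom > 0, Mod(sp$Sxy[sel])^2 / denom, 0)
  mean(pmin(pmax(msc, 0), 1))
}

#' Pairwise coherence feature vector of a region
#'
#' For every unordered electrode pair of the region (lexicographic in
#' montage order): the band coherence computed per epoch, averaged over
#' epochs.  A region with \eqn{n_e} electrodes yields
#' \eqn{n_e(n_e-1)/2} features (21 for a 7-electrode frontal region).
#'
#' @inheritParams singleRunSpectralPower
#' @param band band name from \code{bands}.
#' @param windowS,overlap coherence sub-window parameters, see
#'   [bandCoherence()].
#' @return named numeric vector, one coherence per electrode pair
#'   (\code{"A-B"} names).
#' @export
coherenceFeatureVector <- function(ep, montage, region, band,
                                   bands = defaultBands(),
                                   windowS = 1, overlap = 0.5) {
  stopifnot(is(ep, "EpochArray"))
  bandRow <- bandSubset(bands, band)
  electrodes <- regionElectrodes(montage, region)
  if (length(electrodes) < 2L)
    stop(sprintf("region '%s' has a single electrode; coherence needs a pair",
                 region))
  missing <- setdiff(electrodes, ep@channels)
  if (length(missing) > 0L)
    stop(sprintf("electrode(s) missing: %s", paste(missing, collapse = ", ")))
  pairs <- utils::combn(electrodes, 2)
  n <- nEpochs(ep)
  out <- numeric(ncol(pairs))
  names(out) <- paste(pairs[1, ], pairs[2, ], sep = "-")
  for (p in seq_len(ncol(pairs))) {
    j1 <- match(pairs[1, p], ep@channels)
    j2 <- match(pairs[2, p], ep@channels)
    out[p] <- mean(vapply(seq_len(n), function(i)
      bandCoherence(ep@data[i, j1, ], ep@data[i, j2, ], ep@rate,
                    c(bandRow$low, bandRow$high), windowS, overlap),
      numeric(1)))
  }
  out
}
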