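#' @include preprocess.R bands.R montage.R
NULL

# Periodic Hann taper.
hannTaper <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

# One-sided periodogram of a demeaned, Hann-tapered epoch, normalized so
# that the sum over all bins equals the (tapered) signal power; returns
# power per bin (uV^2) and the bin frequencies.
periodogramPower <- function(x, rate) {
  n <- length(x)
  w <- hannTaper(n)
  X <- stats::fft(w * (x - mean(x)))
  nyq <- floor(n / 2)
  k <- 0:nyq
  coef <- rep(2, nyq + 1)
  coef[1] <- 1
  if (n %% 2 == 0) coef[nyq + 1] <- 1
  p <- coef * Mod(X[k + 1])^2 / (n * sum(w^2))
  list(freq = k * rate / n, power = p)
}

#' Band power of one epoch of one channel
#'
#' Sum of the one-sided periodogram (demeaned, Hann-tapered) over frequency
#' bins \code{low <= f < high}.  The half-open interval means shared band
#' edges are counted exactly once across adjacent bands, and the
#' normalization is such that band powers over a partition of the spectrum
#' sum to the signal power (a unit-amplitude on-bin sinusoid yields about
#' 0.5 uV^2 in its band).
#'
#' @param x numeric vector, one epoch of one channel (microvolts).
#' @param rate sampling rate in Hz.
#' @param band numeric length-2 vector \code{c(low, high)} in Hz, inside
#'   \code{(0, rate/2)}.
#' @return band power in microvolts^2 (non-negative).
#' @examples
#' t <- seq(0, 6, by = 1/500)[-1]
#' epochBandPower(sin(2 * pi * 9 * t), 500, c(8, 10))  # ~0.5
#' @export
epochBandPower <- function(x, rate, band) {
  if (length(x) < 2) stop("epoch must span at least 2 samples")
  if (length(band) != 2 || band[1] >= band[2] || band[1] < 0 ||
      band[2] > rate / 2)
    stop("band must be c(low, high) with 0 <= low < high <= rate/2")
  pg <- periodogramPower(x, rate)
  sel <- pg$freq >= band[1] & pg$freq < band[2]
  if (!any(sel))
    stop(sprintf("band [%g, %g) Hz contains no frequency bins at this epoch length",
                 band[1], band[2]))
  sum(pg$power[sel])
}

#' Per-epoch, per-electrode, per-band spectral powers
#'
#' Runs the periodogram once per epoch x channel and integrates it over each
#' band of the scheme.
#'
#' @param ep an [EpochArray-class].
#' @param bands band-scheme data frame (default [defaultBands()]).
#' @return a [BandPowerTensor-class] (epochs x electrodes x bands).
#' @export
computeBandPowers <- function(ep, bands = defaultBands()) {
  stopifnot(is(ep, "EpochArray"))
  bands <- validateBands(bands)
  d <- dim(ep@data)
  n <- d[1]; nch <- d[2]; L <- d[3]
  w <- hannTaper(L)
  norm <- L * sum(w^2)
  nyq <- floor(L / 2)
  freq <- (0:nyq) * ep@rate / L
  coef <- rep(2, nyq + 1); coef[1] <- 1
  if (L %% 2 == 0) coef[nyq + 1] <- 1
  sel <- lapply(seq_len(nrow(bands)), function(b) {
    s <- which(freq >= bands$low[b] & freq < bands$high[b])
    if (length(s) == 0L)
      stop(sprintf("band '%s' contains no frequency bins", bands$name[b]))
    s
  })
  values <- array(0, dim = c(n, nch, nrow(bands)),
                  dimnames = list(NULL, ep@channels, bands$name))
  for (i in seq_len(n)) {
    seg <- ep@data[i, , , drop = FALSE][1, , , drop = TRUE]
    if (nch == 1L) seg <- matrix(seg, nrow = 1L)
    seg <- seg - rowMeans(seg)
    X <- stats::mvfft(t(seg * rep(w, each = nch)))
    p <- (Mod(X[1:(nyq + 1), , drop = FALSE])^2 * coef) / norm
    for (b in seq_along(sel))
      values[i, , b] <- colSums(p[sel[[b]], , drop = FALSE])
  }
  new("BandPowerTensor", participant = ep@participant, run = ep@run,
      values = values, bands = bands)
}

#' Region-mean power-vector series
#'
#' For each epoch and band, the unweighted mean of the band power over the
#' region's electrodes; epochs become rows of a power-vector matrix whose
#' columns follow the band-scheme order restricted to \code{bandNames}.
#'
#' @param bp a [BandPowerTensor-class].
#' @param montage a [ScalpMontage-class].
#' @param region region name.
#' @param bandNames band subset (character), or NULL for all bands.  A
#'   single band gives one-dimensional power vectors (per-band similarity
#'   mode).
#' @return a [RegionPowerSeries-class].
#' @export
regionPowerSeries <- function(bp, montage, region, bandNames = NULL) {
  stopifnot(is(bp, "BandPowerTensor"), is(montage, "ScalpMontage"))
  electrodes <- regionElectrodes(montage, region)
  have <- dimnames(bp@values)[[2]]
  missing <- setdiff(electrodes, have)
  if (length(missing) > 0L)
    stop(sprintf("electrode(s) not in the band-power tensor: %s",
                 paste(missing, collapse = ", ")))
  bands <- bandSubset(bp@bands, bandNames)
  sub <- bp@values[, electrodes, bands$name, drop = FALSE]
  vectors <- apply(sub, c(1, 3), mean)
  if (is.null(dim(vectors)))
    vectors <- matrix(vectors, ncol = nrow(bands))
  colnames(vectors) <- bands$name
  new("RegionPowerSeries", participant = bp@participant, run = bp@run,
      region = region, bands = bands$name, vectors = vectors)
}
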