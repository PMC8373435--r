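#' @include recording-io.R
NULL

# Windowed-sinc (Hamming) band-pass taps; even order so the band-pass type
# is valid at Nyquist.
firBandpassTaps <- function(low, high, rate, order) {
  order <- as.integer(order)
  if (order %% 2L == 1L) order <- order + 1L
  signal::fir1(order, c(low, high) / (rate / 2), type = "pass",
               window = signal::hamming(order + 1))
}

# Centered (zero-delay) application of a symmetric linear-phase FIR via
# FFT convolution (zero-padded to a 2-3-5-smooth length for speed).
firConvCentered <- function(taps, x) {
  half <- (length(taps) - 1L) %/% 2L
  n <- length(x) + length(taps) - 1L
  N <- stats::nextn(n, c(2, 3, 5))
  y <- Re(stats::fft(stats::fft(c(x, numeric(N - length(x)))) *
                       stats::fft(c(taps, numeric(N - length(taps)))),
                     inverse = TRUE)) / N
  y[(half + 1L):(half + length(x))]
}

# Zero-phase filtering (forward-backward response |H|^2) with reflection
# padding at both ends to suppress edge transients on short inputs.
zeroPhaseFilter <- function(taps, x) {
  n <- length(x)
  pad <- min(n - 1L, 3L * length(taps))
  xp <- c(2 * x[1] - x[pad:1 + 1], x, 2 * x[n] - x[n - (1:pad)])
  y <- firConvCentered(taps, firConvCentered(taps, xp))
  y[(pad + 1):(pad + n)]
}

#' Zero-phase FIR band-pass filter a recording
#'
#' Applies a windowed-sinc (Hamming) band-pass filter forward and backward
#' (zero phase) to every channel.  The default order gives a single-pass
#' group delay of at most 0.5 s (order = sampling rate in samples).
#'
#' @param rec an [EEGRecording-class].
#' @param low,high band edges in Hz; requires 0 < low < high < rate/2.
#' @param order FIR order (number of taps minus one); rounded up to even.
#' @return the filtered [EEGRecording-class], same length as the input.
#' @export
bandpassFilter <- function(rec, low = 0.5, high = 50,
                           order = round(samplingRate(rec))) {
  stopifnot(is(rec, "EEGRecording"))
  rate <- rec@rate
  if (!(low > 0 && low < high))
    stop("band edges must satisfy 0 < low < high")
  if (high >= rate / 2)
    stop(sprintf("high edge %g Hz must be below the Nyquist frequency %g Hz",
                 high, rate / 2))
  taps <- firBandpassTaps(low, high, rate, order)
  if (ncol(rec@samples) <= length(taps) * 3)
    stop("recording too short for the requested filter order")
  filt <- t(apply(rec@samples, 1, function(x) zeroPhaseFilter(taps, x)))
  rownames(filt) <- rec@channels
  rec@samples <- filt
  rec
}

#' Closed-form epoch count
#'
#' Number of complete epochs of \code{epochSamples} samples with a start
#' stride of \code{stepSamples}, in a recording of \code{totalSamples}
#' samples: \code{floor((T - L) / step) + 1}; trailing partial data are
#' discarded.
#'
#' @param totalSamples,epochSamples,stepSamples sample counts.
#' @return integer epoch count (0 when the recording is shorter than one
#'   epoch).
#' @examples
#' epochCount(45000, 3000, 1200)  # 90 s at 500 Hz, 6 s epochs, 60% overlap
#' @export
epochCount <- function(totalSamples, epochSamples, stepSamples) {
  if (totalSamples < epochSamples) return(0L)
  as.integer(floor((totalSamples - epochSamples) / stepSamples) + 1L)
}

#' Segment a recording into fixed-length overlapping epochs
#'
#' Epochs start at multiples of \code{round(epochS * (1 - overlap) * rate)}
#' samples; a 90 s recording at 500 Hz with 6 s epochs and 60% overlap
#' yields 36 epochs.
#'
#' @param rec an [EEGRecording-class].
#' @param epochS epoch length in seconds (default 6).
#' @param overlap overlap fraction in [0, 1) (default 0.6).
#' @return an [EpochArray-class].
#' @export
segmentEpochs <- function(rec, epochS = 6, overlap = 0.6) {
  stopifnot(is(rec, "EEGRecording"))
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  L <- round(epochS * rec@rate)
  if (L < 2) stop("epoch length must span at least 2 samples")
  step <- round(epochS * (1 - overlap) * rec@rate)
  if (step < 1) stop("overlap too large: epoch step is below one sample")
  total <- ncol(rec@samples)
  n <- epochCount(total, L, step)
  if (n < 1L)
    stop(sprintf("recording (%d samples) is shorter than one epoch (%d samples)",
                 total, L))
  data <- array(0, dim = c(n, nrow(rec@samples), L))
  for (i in seq_len(n)) {
    start <- (i - 1L) * step
    data[i, , ] <- rec@samples[, (start + 1):(start + L), drop = FALSE]
  }
  new("EpochArray", participant = rec@participant, run = rec@run,
      data = data, rate = rec@rate, epochS = epochS, overlap = overlap,
      kept = seq_len(n), channels = rec@channels)
}

#' Reject epochs containing large-amplitude samples
#'
#' Removes every epoch in which any channel exceeds \code{threshold}
#' microvolts in absolute value (a deterministic surrogate for visual
#' artifact screening).  Epoch order and the original epoch indices of the
#' kept epochs are preserved.
#'
#' @param ep an [EpochArray-class].
#' @param threshold amplitude threshold in microvolts (default 100).
#' @return the [EpochArray-class] restricted to clean epochs.
#' @export
rejectEpochs <- function(ep, threshold = 100) {
  stopifnot(is(ep, "EpochArray"))
  if (!is.finite(threshold) || threshold <= 0)
    stop("threshold must be a positive number of microvolts")
  peak <- apply(abs(ep@data), 1, max)
  keep <- which(peak <= threshold)
  if (length(keep) == 0L)
    stop(sprintf(
      "all %d epochs exceed %g uV; review the rejection threshold",
      dim(ep@data)[1], threshold))
  ep@data <- ep@data[keep, , , drop = FALSE]
  ep@kept <- ep@kept[keep]
  validObject(ep)
  ep
}
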