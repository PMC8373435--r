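#' @include brseeg-package.R
NULL

GROUP_LEVELS <- c("HC", "MCI", "AD", "unknown")

#' ScalpMontage: named scalp regions and their electrodes
#'
#' Maps region names (for example \code{"frontal"}) to ordered electrode-name
#' vectors in the International 10-20 layout.  Region order is meaningful: it
#' fixes the column order of BRS feature matrices and the tie-break order of
#' feature selection.
#'
#' @slot regions named list of character vectors, one per scalp region.
#' @seealso [defaultMontage()], [loadMontage()]
#' @exportClass ScalpMontage
setClass("ScalpMontage", representation(regions = "list"))

setValidity("ScalpMontage", function(object) {
  r <- object@regions
  if (length(r) == 0L)
    return("montage must contain at least one region")
  if (is.null(names(r)) || any(!nzchar(names(r))) || anyDuplicated(names(r)))
    return("regions must have unique non-empty names")
  for (nm in names(r)) {
    el <- r[[nm]]
    if (!is.character(el) || length(el) == 0L)
      return(sprintf("region '%s' is empty", nm))
    if (anyDuplicated(el))
      return(sprintf("duplicate electrode within region '%s': %s",
                     nm, paste(unique(el[duplicated(el)]), collapse = ", ")))
  }
  TRUE
})

#' EEGRecording: one participant-run of multichannel EEG
#'
#' Samples are stored as an electrodes-by-time matrix in microvolts, with the
#' channel names giving the row order.
#'
#' @slot participant participant identifier.
#' @slot group group label, one of \code{"HC"}, \code{"MCI"}, \code{"AD"},
#'   \code{"unknown"}.
#' @slot run run index, 1 or 2.
#' @slot samples numeric matrix, channels x time, in microvolts.
#' @slot rate sampling rate in Hz.
#' @slot channels ordered channel names matching the matrix rows.
#' @seealso [readRecording()], [simulateCohort()]
#' @exportClass EEGRecording
setClass("EEGRecording",
         representation(participant = "character", group = "character",
                        run = "integer", samples = "matrix",
                        rate = "numeric", channels = "character"))

setValidity("EEGRecording", function(object) {
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    return("sampling rate must be a single positive number")
  if (!object@run %in% c(1L, 2L))
    return("run index must be 1 or 2")
  if (!object@group %in% GROUP_LEVELS)
    return(sprintf("group must be one of %s", paste(GROUP_LEVELS, collapse = ", ")))
  if (length(object@channels) != nrow(object@samples))
    return("channel-name count must equal the sample-matrix row count")
  if (anyDuplicated(object@channels))
    return("duplicate channel names")
  TRUE
})

#' EpochArray: fixed-length (possibly overlapping) epochs of one run
#'
#' @slot participant participant identifier.
#' @slot run run index, 1 or 2.
#' @slot data numeric array, epochs x channels x samples, microvolts.
#' @slot rate sampling rate in Hz.
#' @slot epochS epoch length in seconds.
#' @slot overlap overlap fraction between consecutive epochs, in [0, 1).
#' @slot kept original epoch indices retained (updated by [rejectEpochs()]).
#' @slot channels ordered channel names.
#' @seealso [segmentEpochs()], [rejectEpochs()]
#' @exportClass EpochArray
setClass("EpochArray",
         representation(participant = "character", run = "integer",
                        data = "array", rate = "numeric", epochS = "numeric",
                        overlap = "numeric", kept = "integer",
                        channels = "character"))

setValidity("EpochArray", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L)
    return("data must be a 3-d array (epochs x channels x samples)")
  if (d[1] < 1L)
    return("at least one epoch is required")
  if (length(object@channels) != d[2])
    return("channel-name count must equal dim(data)[2]")
  if (length(object@kept) != d[1])
    return("kept-epoch index count must equal the epoch count")
  if (d[3] != round(object@epochS * object@rate))
    return("epoch sample count must equal round(epochS * rate)")
  if (object@overlap < 0 || object@overlap >= 1)
    return("overlap must be in [0, 1)")
  TRUE
})

#' BandPowerTensor: per-epoch, per-electrode, per-band spectral powers
#'
#' @slot participant participant identifier.
#' @slot run run index.
#' @slot values numeric array, epochs x electrodes x bands, in microvolts^2;
#'   all values are non-negative.
#' @slot bands band scheme data frame (see [defaultBands()]).
#' @seealso [computeBandPowers()]
#' @exportClass BandPowerTensor
setClass("BandPowerTensor",
         representation(participant = "character", run = "integer",
                        values = "array", bands = "data.frame"))

setValidity("BandPowerTensor", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L)
    return("values must be a 3-d array (epochs x electrodes x bands)")
  if (d[3] != nrow(object@bands))
    return("third dimension must match the number of bands")
  if (any(object@values < 0))
    return("band powers must be non-negative")
  TRUE
})

#' RegionPowerSeries: per-epoch region-mean band-power vectors for one run
#'
#' Each row is one epoch's power vector (dimension = number of selected
#' bands, 7 under the default scheme).
#'
#' @slot participant participant identifier.
#' @slot run run index.
#' @slot region scalp region name.
#' @slot bands names of the band subset, in band-scheme order.
#' @slot vectors numeric matrix, epochs x bands.
#' @seealso [regionPowerSeries()], [betweenRunSimilarity()]
#' @exportClass RegionPowerSeries
setClass("RegionPowerSeries",
         representation(participant = "character", run = "integer",
                        region = "character", bands = "character",
                        vectors = "matrix"))

setValidity("RegionPowerSeries", function(object) {
  if (ncol(object@vectors) != length(object@bands))
    return("vector dimension must equal the selected band count")
  if (nrow(object@vectors) < 1L)
    return("at least one epoch is required")
  TRUE
})

setMethod("show", "ScalpMontage", function(object) {
  sizes <- vapply(object@regions, length, integer(1))
  cat(sprintf("ScalpMontage: %d regions, %d electrodes\n",
              length(sizes), sum(sizes)))
  for (nm in names(object@regions))
    cat(sprintf("  %-14s (%d): %s\n", nm, sizes[[nm]],
                paste(object@regions[[nm]], collapse = " ")))
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf(
    "EEGRecording '%s' (group %s, run %d): %d channels x %d samples @ %g Hz (%.1f s)\n",
    object@participant, object@group, object@run, nrow(object@samples),
    ncol(object@samples), object@rate, ncol(object@samples) / object@rate))
})

setMethod("show", "EpochArray", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "EpochArray '%s' run %d: %d epochs x %d channels x %d samples (%g s, overlap %.0f%%)\n",
    object@participant, object@run, d[1], d[2], d[3], object@epochS,
    100 * object@overlap))
})

setMethod("show", "BandPowerTensor", function(object) {
  d <- dim(object@values)
  cat(sprintf("BandPowerTensor '%s' run %d: %d epochs x %d electrodes x %d bands\n",
              object@participant, object@run, d[1], d[2], d[3]))
})

setMethod("show", "RegionPowerSeries", function(object) {
  cat(sprintf("RegionPowerSeries '%s' run %d, region %s: %d epochs x %d bands (%s)\n",
              object@participant, object@run, object@region,
              nrow(object@vectors), length(object@bands),
              paste(object@bands, collapse = ", ")))
})
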