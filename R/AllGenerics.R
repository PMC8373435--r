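#' @include AllClasses.R
NULL

#' Accessors for brseeg S4 objects
#'
#' Small read-only accessors: \code{participantId()}, \code{runIndex()},
#' \code{samplingRate()}, \code{channelNames()}, \code{nEpochs()},
#' \code{regionNames()}, \code{regionElectrodes()}, \code{powerVectors()}.
#'
#' @param x a brseeg S4 object.
#' @param region for \code{regionElectrodes()}, a region name.
#' @return the requested component (identifier, rate, names, counts, or
#'   matrix of power vectors).
#' @name accessors
#' @aliases participantId runIndex samplingRate channelNames nEpochs
#'   regionNames regionElectrodes powerVectors
NULL

#' @rdname accessors
#' @export
setGeneric("participantId", function(x) standardGeneric("participantId"))
#' @rdname accessors
#' @export
setGeneric("runIndex", function(x) standardGeneric("runIndex"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))
#' @rdname accessors
#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))
#' @rdname accessors
#' @export
setGeneric("regionElectrodes", function(x, region) standardGeneric("regionElectrodes"))
#' @rdname accessors
#' @export
setGeneric("powerVectors", function(x) standardGeneric("powerVectors"))

#' @rdname accessors
setMethod("participantId", "EEGRecording", function(x) x@participant)
#' @rdname accessors
setMethod("participantId", "EpochArray", function(x) x@participant)
#' @rdname accessors
setMethod("participantId", "BandPowerTensor", function(x) x@participant)
#' @rdname accessors
setMethod("participantId", "RegionPowerSeries", function(x) x@participant)

#' @rdname accessors
setMethod("runIndex", "EEGRecording", function(x) x@run)
#' @rdname accessors
setMethod("runIndex", "EpochArray", function(x) x@run)
#' @rdname accessors
setMethod("runIndex", "BandPowerTensor", function(x) x@run)
#' @rdname accessors
setMethod("runIndex", "RegionPowerSeries", function(x) x@run)

#' @rdname accessors
setMethod("samplingRate", "EEGRecording", function(x) x@rate)
#' @rdname accessors
setMethod("samplingRate", "EpochArray", function(x) x@rate)

#' @rdname accessors
setMethod("channelNames", "EEGRecording", function(x) x@channels)
#' @rdname accessors
setMethod("channelNames", "EpochArray", function(x) x@channels)

#' @rdname accessors
setMethod("nEpochs", "EpochArray", function(x) dim(x@data)[1])
#' @rdname accessors
setMethod("nEpochs", "BandPowerTensor", function(x) dim(x@values)[1])
#' @rdname accessors
setMethod("nEpochs", "RegionPowerSeries", function(x) nrow(x@vectors))

#' @rdname accessors
setMethod("regionNames", "ScalpMontage", function(x) names(x@regions))
#' @rdname accessors
setMethod("regionElectrodes", "ScalpMontage", function(x, region) {
  if (!region %in% names(x@regions))
    stop(sprintf("unknown region '%s'; montage has: %s", region,
                 paste(names(x@regions), collapse = ", ")))
  x@regions[[region]]
})

#' @rdname accessors
setMethod("powerVectors", "RegionPowerSeries", function(x) x@vectors)
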