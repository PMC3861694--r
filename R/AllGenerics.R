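#' @rdname GridLayout-class
#' @param x a grid, map, recording or result object.
#' @param ... further arguments for methods.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname GridLayout-class
#' @export
setGeneric("gridChannels", function(x) standardGeneric("gridChannels"))

#' @rdname GridLayout-class
#' @export
setGeneric("pitchMm", function(x) standardGeneric("pitchMm"))

#' @rdname GridLayout-class
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' Channel position in the grid coordinate frame
#'
#' @param layout a [GridLayout-class].
#' @param channel one or more channel identifiers.
#' @return numeric matrix with columns \code{x_mm}, \code{y_mm}.
#' @export
setGeneric("channelPosition",
           function(layout, channel) standardGeneric("channelPosition"))

#' Valid grid neighbours of a channel
#'
#' @param layout a [GridLayout-class].
#' @param channel a channel identifier.
#' @param connectivity 4 (edge-sharing) or 8 (edge- or corner-sharing).
#' @return character vector of neighbouring channel identifiers; cells inside
#'   missing blocks are never returned.
#' @export
setGeneric("gridNeighbors",
           function(layout, channel, connectivity = 4)
             standardGeneric("gridNeighbors"))

#' @rdname AmplitudeMap-class
#' @param x an [AmplitudeMap-class].
#' @param form \code{"matrix"} (grid-shaped, NA at invalid cells) or
#'   \code{"channels"} (named vector in layout channel order).
#' @export
setGeneric("mapValues", function(x, form = c("matrix", "channels"))
  standardGeneric("mapValues"))

#' @rdname EMGRecording
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname EMGRecording
#' @export
setGeneric("emgSignals", function(x) standardGeneric("emgSignals"))

#' @rdname EMGRecording
#' @export
setGeneric("forceSignal", function(x) standardGeneric("forceSignal"))

#' @rdname EMGRecording
#' @export
setGeneric("recordingLayout", function(x) standardGeneric("recordingLayout"))

#' @rdname EMGRecording
#' @export
setGeneric("recordingMeta", function(x) standardGeneric("recordingMeta"))

#' Channels above the relative amplitude threshold
#'
#' For an [AmplitudeMap-class], computes the relevant channels of a cluster:
#' those whose raw amplitude is strictly higher than
#' \code{thresholdFraction} times the maximal amplitude within the cluster
#' (the boundary value itself is excluded). For a
#' [LocalizationResult-class], returns the stored relevant channels.
#'
#' @param x an [AmplitudeMap-class] or [LocalizationResult-class].
#' @param ... for the map method: \code{labels} (integer label matrix from
#'   [segmentMap()]), \code{cluster} (cluster id), \code{thresholdFraction}
#'   (default 0.70), \code{thresholdBase} (\code{"cluster"} or
#'   \code{"global"}).
#' @return character vector of channel identifiers; always contains the
#'   cluster's peak channel.
#' @export
setGeneric("relevantChannels", function(x, ...)
  standardGeneric("relevantChannels"))

#' @rdname LocalizationResult-class
#' @param x a [LocalizationResult-class].
#' @export
setGeneric("barycenterMm", function(x) standardGeneric("barycenterMm"))

#' @rdname LocalizationResult-class
#' @export
setGeneric("barycenterNorm", function(x) standardGeneric("barycenterNorm"))

#' @rdname LocalizationResult-class
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname LocalizationResult-class
#' @export
setGeneric("primaryCluster", function(x) standardGeneric("primaryCluster"))
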