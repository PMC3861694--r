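#' Localize the active muscle region of a grid recording
#'
#' Runs the full amplitude-map localization chain on a monopolar grid
#' recording: zero-phase band-pass filtering, bad-channel detection and
#' neighbour interpolation, analysis-epoch selection (steadiest force when a
#' force channel is present, central window otherwise), per-channel RMS map,
#' rank equalization, watershed segmentation, selection of the highest-peak
#' cluster, extraction of the channels above the relative amplitude threshold,
#' their barycenter, and anatomical normalization. Every intermediate is kept
#' in the returned object for auditability.
#'
#' Because every decision in the chain is relative (detection thresholds,
#' rank equalization, the 70% cutoff), the selected channels and the
#' barycenter are invariant under global amplitude scaling of the signals.
#'
#' @param recording an [EMGRecording-class].
#' @param band band-pass c(low, high) Hz; \code{NULL} skips filtering.
#' @param epochS analysis epoch length in s (default 3).
#' @param epochMode \code{"auto"} (force mode when a force channel exists),
#'   \code{"force"}, \code{"central"}, or \code{"all"} (whole recording).
#' @param badChannels manual bad-channel list, unioned with automatic
#'   detection (mirrors operator-driven workflows).
#' @param detectBad run [detectBadChannels()] (default TRUE).
#' @param connectivity watershed/cluster connectivity, 4 or 8 (default 8).
#' @param thresholdFraction relative amplitude cutoff (default 0.70).
#' @param thresholdBase \code{"cluster"} or \code{"global"}; see
#'   [relevantChannels()].
#' @param weighting barycenter weighting, \code{"unweighted"} (default) or
#'   \code{"amplitude"}.
#' @param smooth apply 3x3 mean smoothing to the map before equalization
#'   (default FALSE; useful for very noisy maps).
#' @return a [LocalizationResult-class].
#' @examples
#' layout <- buildGrid(gridSpec(8, 8, 10))
#' rec <- simulateRecording(layout, list(sourceSpec(c(30, 30))),
#'                          noiseRms = 0.1, durationS = 3.5, fs = 1024,
#'                          seed = 7)
#' res <- localize(rec)
#' barycenterMm(res)
#' @export
localize <- function(recording, band = c(10, 400), epochS = 3,
                     epochMode = c("auto", "force", "central", "all"),
                     badChannels = character(), detectBad = TRUE,
                     connectivity = 8, thresholdFraction = 0.70,
                     thresholdBase = "cluster",
                     weighting = "unweighted", smooth = FALSE) {
  epochMode <- match.arg(epochMode)
  layout <- recordingLayout(recording)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE))
  }

  rec <- if (is.null(band)) recording
         else stage("bandpass", bandpassFilter(recording, band))

  bad <- as.character(badChannels)
  if (detectBad)
    bad <- union(bad, stage("bad-channel detection", detectBadChannels(rec)))
  if (length(bad))
    rec <- stage("bad-channel repair", replaceBadChannels(rec, bad))

  if (epochMode == "auto")
    epochMode <- if (is.null(forceSignal(rec))) "central" else "force"
  window <- if (epochMode == "all") {
    new("EpochWindow", startSample = 1L,
        endSample = as.integer(nSamples(rec) + 1L), mode = "all",
        criterionValue = NA_real_)
  } else {
    stage("epoch selection", selectEpoch(rec, epochS = epochS,
                                         mode = epochMode))
  }

  ampMap <- stage("RMS map", computeRmsMap(rec, window))
  mapForEq <- if (smooth) .smooth3x3(ampMap) else ampMap
  eqMap <- stage("equalization",
                 withCallingHandlers(equalizeMap(mapForEq),
                   warning = function(w) invokeRestart("muffleWarning")))
  labels <- stage("watershed", segmentMap(eqMap, connectivity = connectivity))
  primary <- stage("cluster selection", selectPrimaryCluster(labels, ampMap))
  relev <- stage("thresholding",
                 relevantChannels(ampMap, labels = labels, cluster = primary,
                                  thresholdFraction = thresholdFraction,
                                  thresholdBase = thresholdBase))
  bary <- stage("barycenter",
                mapBarycenter(layout, relev, map = ampMap,
                              weighting = weighting))

  meta <- recordingMeta(recording)
  norm <- c(X = NA_real_, Y = NA_real_)
  if (!is.null(meta$forearmLengthMm) && !is.null(meta$forearmCircumferenceMm))
    norm <- stage("normalization",
                  normalizeBarycenter(bary, meta$forearmLengthMm,
                                      meta$forearmCircumferenceMm))

  new("LocalizationResult",
      ampMap = ampMap, equalizedMap = eqMap, labels = labels,
      primaryCluster = as.integer(primary), relevantChannels = relev,
      barycenterMm = unname(bary), barycenterNorm = unname(norm),
      badChannels = bad, epoch = window,
      meta = c(meta, list(config = list(
        band = band, epochS = epochS, epochMode = epochMode,
        connectivity = connectivity, thresholdFraction = thresholdFraction,
        thresholdBase = thresholdBase, weighting = weighting,
        smooth = smooth))))
}

#' @rdname LocalizationResult-class
setMethod("barycenterMm", "LocalizationResult", function(x) x@barycenterMm)

#' @rdname LocalizationResult-class
setMethod("barycenterNorm", "LocalizationResult", function(x) x@barycenterNorm)

#' @rdname LocalizationResult-class
setMethod("clusterLabels", "LocalizationResult", function(x) x@labels)

#' @rdname LocalizationResult-class
setMethod("primaryCluster", "LocalizationResult", function(x) x@primaryCluster)

#' @rdname relevantChannels
setMethod("relevantChannels", "LocalizationResult",
          function(x, ...) x@relevantChannels)

#' Serialize a localization result to JSON
#'
#' Writes the relevant channels, barycenters, repaired channels, epoch and the
#' configuration echo; amplitude and label maps can be exported alongside
#' with [writeMapCsv()].
#'
#' @param result a [LocalizationResult-class].
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeLocalizationJson <- function(result, path) {
  jsonlite::write_json(
    list(
      primary_cluster = result@primaryCluster,
      n_clusters = max(result@labels, na.rm = TRUE),
      relevant_channels = result@relevantChannels,
      barycenter_mm = list(x = result@barycenterMm[1],
                           y = result@barycenterMm[2]),
      barycenter_norm = list(X = result@barycenterNorm[1],
                             Y = result@barycenterNorm[2]),
      bad_channels = result@badChannels,
      epoch = list(start = result@epoch@startSample,
                   end = result@epoch@endSample,
                   mode = result@epoch@mode),
      meta = result@meta),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Export a grid-shaped matrix (amplitude or label map) as CSV
#'
#' One CSV row per grid row; invalid cells are written as empty fields.
#'
#' @param values numeric or integer nRows x nCols matrix (NA at invalid
#'   cells), e.g. \code{mapValues(map)} or \code{clusterLabels(result)}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeMapCsv <- function(values, path) {
  utils::write.table(values, path, sep = ",", na = "",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
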