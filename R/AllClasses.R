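#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Electrode grid specification
#'
#' Describes a planar high-density EMG electrode grid as a full
#' \code{nRows} x \code{nCols} lattice with constant inter-electrode distance
#' (pitch), from which rectangular blocks of cells may be removed (the missing
#' corner groups of commercially shaped grids). One column is designated the
#' anatomical reference column: the medio-lateral origin of the coordinate
#' frame, placed on the skin landmark line during acquisition (for the packaged
#' forearm layout, the lateral epicondyle-ulnar styloid line).
#'
#' @slot nRows integer, number of grid rows (proximal to distal).
#' @slot nCols integer, number of grid columns (ulnar to radial).
#' @slot pitchMm numeric, distance in mm between adjacent electrodes.
#' @slot missingBlocks list of blocks, each \code{list(rows = c(first, last),
#'   cols = c(first, last))}, removed from the lattice.
#' @slot referenceCol integer, column aligned with the anatomical reference
#'   line; x coordinates are measured from this column.
#'
#' @seealso [gridSpec()], [buildGrid()], [standardGrid128()]
#' @export
setClass("GridSpec",
  representation(
    nRows = "integer",
    nCols = "integer",
    pitchMm = "numeric",
    missingBlocks = "list",
    referenceCol = "integer"
  )
)

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@nRows) != 1L || is.na(object@nRows) || object@nRows < 1L)
    msg <- c(msg, "nRows must be a single integer >= 1")
  if (length(object@nCols) != 1L || is.na(object@nCols) || object@nCols < 1L)
    msg <- c(msg, "nCols must be a single integer >= 1")
  if (length(object@pitchMm) != 1L || !is.finite(object@pitchMm) ||
      object@pitchMm <= 0)
    msg <- c(msg, "pitchMm must be a single positive number")
  if (length(object@referenceCol) != 1L || is.na(object@referenceCol) ||
      object@referenceCol < 1L ||
      (length(object@nCols) == 1L && !is.na(object@nCols) &&
       object@referenceCol > object@nCols))
    msg <- c(msg, "referenceCol must lie within [1, nCols]")
  occupied <- NULL
  for (b in object@missingBlocks) {
    if (!is.list(b) || !all(c("rows", "cols") %in% names(b)) ||
        length(b$rows) != 2L || length(b$cols) != 2L) {
      msg <- c(msg, "each missing block needs rows = c(first, last) and cols = c(first, last)")
      next
    }
    if (b$rows[1] > b$rows[2] || b$cols[1] > b$cols[2] ||
        b$rows[1] < 1L || b$cols[1] < 1L ||
        b$rows[2] > object@nRows || b$cols[2] > object@nCols) {
      msg <- c(msg, "missing block outside the grid or with reversed ranges")
      next
    }
    cells <- as.vector(outer(seq(b$rows[1], b$rows[2]),
                             seq(b$cols[1], b$cols[2]),
                             function(r, c) (r - 1L) * object@nCols + c))
    if (any(cells %in% occupied))
      msg <- c(msg, "missing blocks overlap")
    occupied <- c(occupied, cells)
  }
  if (length(msg)) msg else TRUE
})

#' Realized electrode grid layout
#'
#' The enumerated layout of a [GridSpec-class]: one channel per non-excluded
#' cell, in row-major order (proximal to distal, then ulnar to radial), with
#' planar positions in mm. The coordinate convention is
#' \code{x = (col - referenceCol) * pitch} (positive toward the radial side)
#' and \code{y = (row - 1) * pitch} (positive distally, origin at the proximal
#' row), so normalized barycenters are directly comparable across subjects.
#'
#' @slot spec the generating [GridSpec-class].
#' @slot channels character vector of channel identifiers (\code{"rRRcCC"}).
#' @slot row,col integer vectors, grid cell per channel.
#' @slot x,y numeric vectors, planar position in mm per channel.
#' @slot validMask logical nRows x nCols matrix, TRUE where an electrode exists.
#'
#' @seealso [buildGrid()], [channelPosition()], [gridNeighbors()]
#' @export
setClass("GridLayout",
  representation(
    spec = "GridSpec",
    channels = "character",
    row = "integer",
    col = "integer",
    x = "numeric",
    y = "numeric",
    validMask = "matrix"
  )
)

setValidity("GridLayout", function(object) {
  msg <- character()
  n <- length(object@channels)
  if (anyDuplicated(object@channels))
    msg <- c(msg, "duplicated channel identifiers")
  if (length(object@row) != n || length(object@col) != n ||
      length(object@x) != n || length(object@y) != n)
    msg <- c(msg, "channel attribute vectors must have equal length")
  if (!is.logical(object@validMask) ||
      !identical(dim(object@validMask),
                 c(as.integer(object@spec@nRows), as.integer(object@spec@nCols))))
    msg <- c(msg, "validMask must be a logical nRows x nCols matrix")
  else {
    if (sum(object@validMask) != n)
      msg <- c(msg, "validMask count disagrees with channel count")
    if (n > 0 && !all(object@validMask[cbind(object@row, object@col)]))
      msg <- c(msg, "some channels map to invalid cells")
    if (anyDuplicated(cbind(object@row, object@col)))
      msg <- c(msg, "two channels share a grid cell")
  }
  if (length(msg)) msg else TRUE
})

#' Grid EMG recording
#'
#' A multichannel monopolar surface EMG recording on an electrode grid,
#' represented as a \linkS4class{SummarizedExperiment} with channels as rows
#' (assay \code{"emg"}, channels x samples), grid geometry in \code{rowData}
#' (row, col, x_mm, y_mm) and the optional simultaneous force signal as the
#' \code{force} column of \code{colData}. Sampling rate, task/subject/anatomy
#' metadata, the [GridLayout-class] and (for synthetic data) the ground truth
#' live in \code{metadata()}.
#'
#' @seealso [EMGRecording()], [simulateRecording()], [bandpassFilter()],
#'   [localize()]
#' @export
setClass("EMGRecording", contains = "SummarizedExperiment")

setValidity("EMGRecording", function(object) {
  msg <- character()
  md <- metadata(object)
  fs <- md$fs
  if (is.null(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    msg <- c(msg, "metadata(object)$fs must be a single positive sampling rate")
  if (!"emg" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'emg' is required")
  layout <- md$layout
  if (is.null(layout) || !is(layout, "GridLayout"))
    msg <- c(msg, "metadata(object)$layout must be a GridLayout")
  else if (nrow(object) != length(layout@channels))
    msg <- c(msg, "row count must equal the layout channel count")
  if (length(msg)) msg else TRUE
})

#' Monopolar RMS amplitude map
#'
#' Per-channel RMS amplitude over an analysis epoch, arranged on the electrode
#' grid as an nRows x nCols matrix with \code{NA} at invalid (missing-block)
#' cells. The same container holds equalized maps, whose values lie in
#' \code{[0, 1]}.
#'
#' @slot values numeric matrix, amplitude per grid cell; NA where no electrode.
#' @slot layout the [GridLayout-class] the map is arranged on.
#' @slot equalized logical, TRUE after rank equalization.
#'
#' @seealso [computeRmsMap()], [equalizeMap()], [segmentMap()]
#' @export
setClass("AmplitudeMap",
  representation(
    values = "matrix",
    layout = "GridLayout",
    equalized = "logical"
  ),
  prototype(equalized = FALSE)
)

setValidity("AmplitudeMap", function(object) {
  msg <- character()
  mask <- object@layout@validMask
  if (!identical(dim(object@values), dim(mask)))
    msg <- c(msg, "values must have the grid's dimensions")
  else {
    if (any(is.na(object@values[mask])))
      msg <- c(msg, "values must be defined on every valid cell")
    if (any(!is.na(object@values[!mask])))
      msg <- c(msg, "values must be NA on invalid cells")
    if (any(object@values[mask] < 0))
      msg <- c(msg, "amplitudes must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Analysis epoch window
#'
#' A half-open sample range \code{[startSample, endSample)} selected for
#' amplitude analysis, with the selection criterion value (sliding-window
#' force standard deviation) when the steadiest-force mode chose it.
#'
#' @slot startSample integer, first sample (1-based, inclusive).
#' @slot endSample integer, one past the last sample (exclusive).
#' @slot mode character, \code{"force"} (steadiest force) or \code{"central"}.
#' @slot criterionValue numeric, attained force SD (NA in central mode).
#'
#' @seealso [selectEpoch()]
#' @export
setClass("EpochWindow",
  representation(
    startSample = "integer",
    endSample = "integer",
    mode = "character",
    criterionValue = "numeric"
  )
)

setValidity("EpochWindow", function(object) {
  if (object@startSample < 1L || object@endSample <= object@startSample)
    "need 1 <= startSample < endSample" else TRUE
})

#' Localization of the active region of an amplitude map
#'
#' Full, auditable result of the amplitude-map localization chain: the RMS and
#' equalized maps, watershed cluster labels, the selected (highest-peak)
#' cluster, the relevant channels above the relative amplitude threshold, and
#' the barycenter of their positions in mm and in anatomically normalized
#' coordinates (X = x / forearm circumference, Y = y / forearm length).
#'
#' @slot ampMap raw RMS [AmplitudeMap-class].
#' @slot equalizedMap rank-equalized [AmplitudeMap-class].
#' @slot labels integer matrix of cluster labels (NA at invalid cells).
#' @slot primaryCluster integer, id of the highest-peak cluster.
#' @slot relevantChannels character, channels above the threshold.
#' @slot barycenterMm numeric c(x, y) in mm in the grid frame.
#' @slot barycenterNorm numeric c(X, Y), dimensionless; NA when the recording
#'   carries no anatomy metadata.
#' @slot badChannels character, channels detected/declared bad and repaired.
#' @slot epoch the [EpochWindow-class] analyzed.
#' @slot meta list, subject/task/level/anatomy metadata echoed from the
#'   recording plus the configuration used.
#'
#' @seealso [localize()], [buildBarycenterTable()]
#' @export
setClass("LocalizationResult",
  representation(
    ampMap = "AmplitudeMap",
    equalizedMap = "AmplitudeMap",
    labels = "matrix",
    primaryCluster = "integer",
    relevantChannels = "character",
    barycenterMm = "numeric",
    barycenterNorm = "numeric",
    badChannels = "character",
    epoch = "EpochWindow",
    meta = "list"
  )
)

setValidity("LocalizationResult", function(object) {
  msg <- character()
  if (length(object@barycenterMm) != 2L)
    msg <- c(msg, "barycenterMm must be c(x, y)")
  if (length(object@barycenterNorm) != 2L)
    msg <- c(msg, "barycenterNorm must be c(X, Y)")
  if (length(object@relevantChannels) < 1L)
    msg <- c(msg, "at least one relevant channel (the peak) is required")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GridSpec", function(object) {
  cat("GridSpec:", object@nRows, "x", object@nCols,
      "lattice, pitch", object@pitchMm, "mm,",
      length(object@missingBlocks), "missing block(s),",
      "reference column", object@referenceCol, "\n")
})

setMethod("show", "GridLayout", function(object) {
  cat("GridLayout with", length(object@channels), "electrodes on a",
      object@spec@nRows, "x", object@spec@nCols, "grid (pitch",
      object@spec@pitchMm, "mm)\n")
  cat("  x range [mm]:", paste(range(object@x), collapse = " .. "),
      " y range [mm]:", paste(range(object@y), collapse = " .. "), "\n")
})

setMethod("show", "AmplitudeMap", function(object) {
  v <- object@values[object@layout@validMask]
  cat(if (object@equalized) "Equalized amplitude map" else "RMS amplitude map",
      "on", length(v), "channels; range",
      sprintf("[%.4g, %.4g]", min(v), max(v)), "\n")
})

setMethod("show", "EpochWindow", function(object) {
  cat(sprintf("EpochWindow [%d, %d) mode=%s", object@startSample,
              object@endSample, object@mode))
  if (is.finite(object@criterionValue))
    cat(sprintf(" (force SD %.4g)", object@criterionValue))
  cat("\n")
})

setMethod("show", "LocalizationResult", function(object) {
  cat("LocalizationResult\n")
  cat("  primary cluster:", object@primaryCluster, "of",
      max(object@labels, na.rm = TRUE), "\n")
  cat("  relevant channels:", length(object@relevantChannels), "\n")
  cat(sprintf("  barycenter [mm]: (%.2f, %.2f)\n",
              object@barycenterMm[1], object@barycenterMm[2]))
  if (all(is.finite(object@barycenterNorm)))
    cat(sprintf("  normalized (X, Y): (%.4f, %.4f)\n",
                object@barycenterNorm[1], object@barycenterNorm[2]))
  if (length(object@badChannels))
    cat("  repaired channels:", paste(object@badChannels, collapse = ", "), "\n")
})
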