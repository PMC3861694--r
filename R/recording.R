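#' Construct a grid EMG recording
#'
#' @param data numeric samples x channels matrix of monopolar EMG, channel
#'   order matching \code{gridChannels(layout)}.
#' @param layout the [GridLayout-class] the channels are arranged on.
#' @param fs sampling rate in samples/s (2048 for the standard amplifier).
#' @param force optional per-sample force signal (same sample count).
#' @param meta named list of metadata: \code{subject}, \code{task},
#'   \code{levelPctMVC}, \code{forearmLengthMm}, \code{forearmCircumferenceMm}.
#' @param groundTruth optional list describing synthetic provenance (sources,
#'   noise RMS, injected bad channels, seed).
#' @return an [EMGRecording-class].
#' @export
EMGRecording <- function(data, layout, fs, force = NULL, meta = list(),
                         groundTruth = NULL) {
  data <- as.matrix(data)
  if (ncol(data) != nChannels(layout))
    stop("data must have one column per layout channel", call. = FALSE)
  if (!is.null(force) && length(force) != nrow(data))
    stop("force must have one value per sample", call. = FALSE)
  assay <- t(data)
  dimnames(assay) <- list(gridChannels(layout), NULL)
  cd <- if (is.null(force)) S4Vectors::DataFrame(matrix(nrow = nrow(data), ncol = 0))
        else S4Vectors::DataFrame(force = as.numeric(force))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(emg = assay),
    rowData = S4Vectors::DataFrame(
      row = layout@row, col = layout@col,
      x_mm = layout@x, y_mm = layout@y,
      row.names = gridChannels(layout)),
    colData = cd,
    metadata = list(fs = as.numeric(fs), layout = layout, meta = meta,
                    groundTruth = groundTruth))
  new("EMGRecording", se)
}

#' @rdname EMGRecording
#' @param x an [EMGRecording-class].
setMethod("samplingRate", "EMGRecording", function(x) metadata(x)$fs)

#' @rdname EMGRecording
setMethod("emgSignals", "EMGRecording", function(x)
  t(SummarizedExperiment::assay(x, "emg")))

#' @rdname EMGRecording
setMethod("forceSignal", "EMGRecording", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("force" %in% colnames(cd)) cd$force else NULL
})

#' @rdname EMGRecording
setMethod("recordingLayout", "EMGRecording", function(x) metadata(x)$layout)

#' @rdname EMGRecording
setMethod("recordingMeta", "EMGRecording", function(x) metadata(x)$meta)

#' @rdname EMGRecording
setMethod("nChannels", "EMGRecording", function(x) nrow(x))

#' Number of samples in a recording
#' @param x an [EMGRecording-class].
#' @return integer sample count.
#' @export
nSamples <- function(x) ncol(x)

.replaceEmg <- function(x, data) {
  # data: samples x channels; preserves all metadata
  a <- t(data)
  dimnames(a) <- dimnames(SummarizedExperiment::assay(x, "emg"))
  SummarizedExperiment::assay(x, "emg") <- a
  x
}

#' Write / read a recording as CSV plus JSON sidecar
#'
#' The CSV holds one row per sample, one column per channel (header = channel
#' identifiers) plus a final \code{force} column when a force signal is
#' present. The sidecar \code{<path>.json} records the sampling rate, the grid
#' specification, metadata and any synthetic ground truth, making the pair
#' self-describing.
#'
#' @param recording an [EMGRecording-class].
#' @param path CSV file path; the sidecar is written next to it.
#' @param digits significant digits used for the CSV (default 8).
#' @return \code{writeRecordingCsv}: the path, invisibly.
#' @export
writeRecordingCsv <- function(recording, path, digits = 8) {
  df <- as.data.frame(signif(emgSignals(recording), digits))
  f <- forceSignal(recording)
  if (!is.null(f)) df$force <- signif(f, digits)
  utils::write.csv(df, path, row.names = FALSE)
  md <- metadata(recording)
  sidecar <- list(
    fs = md$fs,
    grid_spec = list(
      n_rows = md$layout@spec@nRows, n_cols = md$layout@spec@nCols,
      pitch_mm = md$layout@spec@pitchMm,
      missing_blocks = lapply(md$layout@spec@missingBlocks, function(b)
        list(rows = b$rows, cols = b$cols)),
      reference_col = md$layout@spec@referenceCol),
    meta = md$meta,
    ground_truth = md$groundTruth)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeRecordingCsv
#' @return \code{readRecordingCsv}: the reconstructed [EMGRecording-class].
#' @export
readRecordingCsv <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"),
                                 simplifyVector = TRUE)
  gs <- sidecar$grid_spec
  blocks <- gs$missing_blocks
  if (is.data.frame(blocks))
    blocks <- lapply(seq_len(nrow(blocks)), function(i)
      list(rows = unlist(blocks$rows[i]), cols = unlist(blocks$cols[i])))
  layout <- buildGrid(gridSpec(gs$n_rows, gs$n_cols, gs$pitch_mm,
                               missingBlocks = blocks,
                               referenceCol = gs$reference_col))
  df <- utils::read.csv(path, check.names = FALSE)
  force <- NULL
  if ("force" %in% colnames(df)) {
    force <- df$force
    df$force <- NULL
  }
  data <- as.matrix(df)
  if (!identical(colnames(data), gridChannels(layout)))
    stop("CSV channel header does not match the layout", call. = FALSE)
  gt <- sidecar$ground_truth
  EMGRecording(data, layout, sidecar$fs, force = force,
               meta = as.list(sidecar$meta),
               groundTruth = if (length(gt)) gt else NULL)
}
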