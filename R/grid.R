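#' Create an electrode grid specification
#'
#' @param nRows,nCols lattice dimensions.
#' @param pitchMm inter-electrode distance in mm (10 for the standard grid).
#' @param missingBlocks list of rectangular exclusions, each
#'   \code{list(rows = c(first, last), cols = c(first, last))}.
#' @param referenceCol column aligned with the anatomical reference line.
#' @return a validated [GridSpec-class].
#' @examples
#' gridSpec(12, 12, 10,
#'          missingBlocks = list(list(rows = c(1, 2),  cols = c(1, 4)),
#'                               list(rows = c(11, 12), cols = c(1, 4))),
#'          referenceCol = 3)
#' @export
gridSpec <- function(nRows, nCols, pitchMm = 10,
                     missingBlocks = list(), referenceCol = 1L) {
  new("GridSpec",
      nRows = as.integer(nRows), nCols = as.integer(nCols),
      pitchMm = as.numeric(pitchMm),
      missingBlocks = lapply(missingBlocks, function(b)
        list(rows = as.integer(b$rows), cols = as.integer(b$cols))),
      referenceCol = as.integer(referenceCol))
}

#' Build the electrode layout for a grid specification
#'
#' Enumerates every non-excluded cell of the lattice in row-major order
#' (proximal-to-distal rows, ulnar-to-radial columns within a row) and assigns
#' planar positions: \code{x = (col - referenceCol) * pitch},
#' \code{y = (row - 1) * pitch}. Channel identifiers are \code{"rRRcCC"}.
#'
#' @param spec a [GridSpec-class].
#' @return a [GridLayout-class].
#' @examples
#' layout <- buildGrid(gridSpec(12, 12, 10))
#' nChannels(layout)  # 144
#' @export
buildGrid <- function(spec) {
  validObject(spec)
  mask <- matrix(TRUE, spec@nRows, spec@nCols)
  for (b in spec@missingBlocks)
    mask[seq(b$rows[1], b$rows[2]), seq(b$cols[1], b$cols[2])] <- FALSE
  idx <- which(t(mask))  # row-major enumeration
  col <- as.integer((idx - 1L) %% spec@nCols + 1L)
  row <- as.integer((idx - 1L) %/% spec@nCols + 1L)
  new("GridLayout",
      spec = spec,
      channels = sprintf("r%02dc%02d", row, col),
      row = row, col = col,
      x = (col - spec@referenceCol) * spec@pitchMm,
      y = (row - 1L) * spec@pitchMm,
      validMask = mask)
}

#' @rdname GridLayout-class
setMethod("nChannels", "GridLayout", function(x) length(x@channels))

#' @rdname GridLayout-class
setMethod("gridChannels", "GridLayout", function(x) x@channels)

#' @rdname GridLayout-class
setMethod("pitchMm", "GridLayout", function(x) x@spec@pitchMm)

#' @rdname GridLayout-class
setMethod("validMask", "GridLayout", function(x) x@validMask)

.channelIndex <- function(layout, channel) {
  i <- match(channel, layout@channels)
  if (anyNA(i))
    stop("unknown channel(s): ",
         paste(channel[is.na(i)], collapse = ", "), call. = FALSE)
  i
}

#' @rdname channelPosition
setMethod("channelPosition", "GridLayout", function(layout, channel) {
  i <- .channelIndex(layout, channel)
  cbind(x_mm = layout@x[i], y_mm = layout@y[i])
})

#' @rdname gridNeighbors
setMethod("gridNeighbors", "GridLayout",
  function(layout, channel, connectivity = 4) {
    connectivity <- as.integer(connectivity)
    if (!connectivity %in% c(4L, 8L))
      stop("connectivity must be 4 or 8", call. = FALSE)
    i <- .channelIndex(layout, channel)
    if (length(i) != 1L) stop("one channel at a time", call. = FALSE)
    dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)[seq_len(connectivity)]
    dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)[seq_len(connectivity)]
    r <- layout@row[i] + dr
    c <- layout@col[i] + dc
    ok <- r >= 1L & r <= layout@spec@nRows & c >= 1L & c <= layout@spec@nCols
    ok[ok] <- layout@validMask[cbind(r[ok], c[ok])]
    sprintf("r%02dc%02d", r[ok], c[ok])
  })

#' Read / write grid specifications as JSON
#'
#' The JSON dialect uses keys \code{n_rows}, \code{n_cols}, \code{pitch_mm},
#' \code{missing_blocks} (objects with \code{rows}, \code{cols} two-element
#' ranges) and \code{reference_col}. The packaged file
#' \code{extdata/grid128.json} holds the standard 128-electrode forearm
#' layout: a 12 x 12 lattice at 10 mm pitch with two 4-column x 2-row blocks
#' removed at the ulnar proximal and distal corners, reference column 3.
#'
#' @param path file path.
#' @return \code{readGridSpec}: a [GridSpec-class].
#' @export
readGridSpec <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  blocks <- list()
  mb <- j$missing_blocks
  if (!is.null(mb)) {
    if (is.data.frame(mb)) {
      blocks <- lapply(seq_len(nrow(mb)), function(i)
        list(rows = unlist(mb$rows[i]), cols = unlist(mb$cols[i])))
    } else {
      blocks <- lapply(mb, function(b) list(rows = b$rows, cols = b$cols))
    }
  }
  gridSpec(j$n_rows, j$n_cols, j$pitch_mm,
           missingBlocks = blocks, referenceCol = j$reference_col)
}

#' @rdname readGridSpec
#' @param spec a [GridSpec-class] to serialize.
#' @export
writeGridSpec <- function(spec, path) {
  validObject(spec)
  jsonlite::write_json(
    list(n_rows = spec@nRows, n_cols = spec@nCols, pitch_mm = spec@pitchMm,
         missing_blocks = lapply(spec@missingBlocks, function(b)
           list(rows = b$rows, cols = b$cols)),
         reference_col = spec@referenceCol),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname readGridSpec
#' @return \code{standardGrid128}: the built 128-electrode [GridLayout-class].
#' @examples
#' nChannels(standardGrid128())  # 128
#' @export
standardGrid128 <- function() {
  buildGrid(readGridSpec(
    system.file("extdata", "grid128.json", package = "emgrid",
                mustWork = TRUE)))
}
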