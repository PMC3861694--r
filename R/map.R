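#' Compute the monopolar RMS amplitude map
#'
#' Per-channel root mean square over the analysis window, arranged on the
#' electrode grid. This is the monopolar amplitude distribution the
#' localization chain operates on.
#'
#' @param recording an [EMGRecording-class].
#' @param window an [EpochWindow-class]; \code{NULL} uses the whole recording.
#' @return an [AmplitudeMap-class].
#' @export
computeRmsMap <- function(recording, window = NULL) {
  layout <- recordingLayout(recording)
  data <- emgSignals(recording)
  if (!is.null(window)) {
    validObject(window)
    if (window@endSample - 1L > nrow(data))
      stop("epoch window exceeds the recording", call. = FALSE)
    data <- data[window@startSample:(window@endSample - 1L), , drop = FALSE]
  }
  if (nrow(data) == 0L)
    stop("empty analysis window", call. = FALSE)
  rms <- sqrt(colMeans(data^2))
  vals <- matrix(NA_real_, layout@spec@nRows, layout@spec@nCols)
  vals[cbind(layout@row, layout@col)] <- rms
  new("AmplitudeMap", values = vals, layout = layout, equalized = FALSE)
}

#' @rdname mapValues
#' @param x an [AmplitudeMap-class].
#' @param form \code{"matrix"} or \code{"channels"}.
setMethod("mapValues", "AmplitudeMap", function(x, form = c("matrix",
                                                            "channels")) {
  form <- match.arg(form)
  if (form == "matrix") return(x@values)
  l <- x@layout
  stats::setNames(x@values[cbind(l@row, l@col)], l@channels)
})

#' @rdname AmplitudeMap-class
setMethod("nChannels", "AmplitudeMap", function(x) length(x@layout@channels))

#' Rank-based equalization of an amplitude map
#'
#' Maps the valid-cell amplitudes onto \code{[0, 1]} by their ranks
#' (histogram equalization): ties share a value, the order of distinct values
#' is preserved exactly, and the result is invariant under any strictly
#' increasing transform of the input — which makes the subsequent watershed
#' depend only on the topography of the map, not on its scale. A constant map
#' cannot be equalized; it is returned as all 0.5 with a warning and yields a
#' single cluster downstream.
#'
#' @param map an [AmplitudeMap-class].
#' @return the equalized [AmplitudeMap-class] (values in \code{[0, 1]}).
#' @export
equalizeMap <- function(map) {
  mask <- map@layout@validMask
  v <- map@values[mask]
  if (length(v) < 2L)
    stop("equalization needs at least 2 valid channels", call. = FALSE)
  r <- rank(v, ties.method = "average")
  if (max(r) == min(r)) {
    warning("constant amplitude map: equalization is degenerate")
    eq <- rep(0.5, length(v))
  } else {
    eq <- (r - min(r)) / (max(r) - min(r))
  }
  out <- map
  out@values[mask] <- eq
  out@equalized <- TRUE
  out
}

# 3x3 mean smoothing over valid cells (optional pre-watershed denoising).
.smooth3x3 <- function(map) {
  mask <- map@layout@validMask
  v <- map@values
  nr <- nrow(v); nc <- ncol(v)
  out <- v
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    rr <- max(1, r - 1):min(nr, r + 1)
    cc <- max(1, c - 1):min(nc, c + 1)
    nb <- v[rr, cc]
    out[r, c] <- mean(nb[!is.na(nb)])
  }
  res <- map
  res@values <- out
  res
}

# Neighbour offsets for the given connectivity.
.offsets <- function(connectivity) {
  if (connectivity == 4)
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  else
    cbind(dr = c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
          dc = c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L))
}

#' Watershed segmentation of an (equalized) amplitude map
#'
#' Partitions the valid cells of the map into clusters, one per regional
#' maximum: flooding the negated map from its regional maxima is realized as
#' deterministic steepest ascent — every cell follows its strictly largest
#' neighbour until it reaches a regional-maximum plateau, and all cells
#' draining to the same plateau form one cluster. Equal-valued plateaus are
#' handled as units; ties in the ascent direction are broken toward the
#' smallest row-major cell index, so the segmentation is fully deterministic.
#' Invalid (missing-block) cells are excluded from flooding and stay
#' unlabelled. A constant map yields a single cluster covering all valid
#' cells.
#'
#' @param map an [AmplitudeMap-class], normally the output of [equalizeMap()].
#' @param connectivity 4 or 8 (default 8) for both plateaus and ascent.
#' @return integer nRows x nCols label matrix; clusters are numbered from 1 in
#'   row-major order of their peak plateau, \code{NA} at invalid cells.
#' @export
segmentMap <- function(map, connectivity = 8) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 or 8", call. = FALSE)
  mask <- map@layout@validMask
  v <- map@values
  nr <- nrow(v); nc <- ncol(v)
  off <- .offsets(connectivity)
  cellId <- function(r, c) (r - 1L) * nc + c  # row-major index

  valid <- which(mask, arr.ind = TRUE)
  valid <- valid[order(cellId(valid[, 1], valid[, 2])), , drop = FALSE]
  nv <- nrow(valid)
  idOf <- matrix(NA_integer_, nr, nc)   # cell -> index into `valid`
  idOf[valid] <- seq_len(nv)

  # 1. plateaus: connected components of equal-valued adjacent valid cells
  plateau <- integer(nv)
  np <- 0L
  for (i in seq_len(nv)) {
    if (plateau[i] > 0L) next
    np <- np + 1L
    queue <- i
    plateau[i] <- np
    while (length(queue)) {
      k <- queue[1]; queue <- queue[-1]
      r0 <- valid[k, 1]; c0 <- valid[k, 2]
      for (o in seq_len(nrow(off))) {
        r1 <- r0 + off[o, 1]; c1 <- c0 + off[o, 2]
        if (r1 < 1L || r1 > nr || c1 < 1L || c1 > nc) next
        j <- idOf[r1, c1]
        if (is.na(j) || plateau[j] > 0L) next
        if (v[r1, c1] == v[r0, c0]) {
          plateau[j] <- np
          queue <- c(queue, j)
        }
      }
    }
  }

  # 2. each plateau drains to the highest strictly greater neighbouring cell
  #    (tie: smallest row-major index); plateaus without one are seeds
  parent <- integer(np)           # 0 = regional-maximum plateau
  firstCell <- integer(np)        # smallest row-major cell id, for ordering
  for (p in seq_len(np)) {
    members <- which(plateau == p)
    firstCell[p] <- min(cellId(valid[members, 1], valid[members, 2]))
    bestVal <- -Inf; bestId <- NA_integer_; bestPlateau <- 0L
    pv <- v[valid[members[1], 1], valid[members[1], 2]]
    for (k in members) {
      r0 <- valid[k, 1]; c0 <- valid[k, 2]
      for (o in seq_len(nrow(off))) {
        r1 <- r0 + off[o, 1]; c1 <- c0 + off[o, 2]
        if (r1 < 1L || r1 > nr || c1 < 1L || c1 > nc) next
        j <- idOf[r1, c1]
        if (is.na(j)) next
        val <- v[r1, c1]
        if (val > pv) {
          id <- cellId(r1, c1)
          if (val > bestVal || (val == bestVal && id < bestId)) {
            bestVal <- val; bestId <- id; bestPlateau <- plateau[j]
          }
        }
      }
    }
    parent[p] <- bestPlateau
  }

  # 3. resolve drainage chains to their root (regional-maximum) plateau
  root <- integer(np)
  findRoot <- function(p) {
    path <- integer(0)
    while (parent[p] != 0L && root[p] == 0L) {
      path <- c(path, p)
      p <- parent[p]
    }
    r <- if (root[p] != 0L) root[p] else p
    root[path] <<- r
    root[p] <<- r
    r
  }
  for (p in seq_len(np)) findRoot(p)

  # 4. number clusters in row-major order of their peak plateau
  seeds <- sort(unique(root))
  ord <- seeds[order(firstCell[seeds])]
  clusterOf <- integer(np)
  clusterOf[ord] <- seq_along(ord)

  labels <- matrix(NA_integer_, nr, nc)
  labels[valid] <- clusterOf[root[plateau]]
  labels
}

#' Select the primary (highest-peak) cluster
#'
#' Among the watershed clusters, returns the id of the one whose maximal raw
#' (un-equalized) amplitude is largest — the cluster taken to represent the
#' main active muscle region; other, lower-amplitude clusters (e.g.
#' crosstalk) are ignored. Exact ties are broken toward the lowest cluster id.
#'
#' @param labels integer label matrix from [segmentMap()].
#' @param map the raw (un-equalized) [AmplitudeMap-class].
#' @return integer cluster id.
#' @export
selectPrimaryCluster <- function(labels, map) {
  ids <- sort(unique(labels[!is.na(labels)]))
  if (length(ids) == 0L)
    stop("empty segmentation: no clusters", call. = FALSE)
  peaks <- vapply(ids, function(k)
    max(map@values[!is.na(labels) & labels == k]), numeric(1))
  ids[which.max(peaks)]  # which.max returns the first (lowest id) on ties
}

#' @rdname relevantChannels
#' @param labels integer label matrix from [segmentMap()].
#' @param cluster cluster id (normally from [selectPrimaryCluster()]).
#' @param thresholdFraction relative amplitude cutoff (default 0.70).
#' @param thresholdBase \code{"cluster"} references the maximum within the
#'   cluster (the default reading of the per-cluster rule);
#'   \code{"global"} references the whole-map maximum, for sensitivity
#'   analyses.
setMethod("relevantChannels", "AmplitudeMap",
  function(x, labels, cluster, thresholdFraction = 0.70,
           thresholdBase = c("cluster", "global")) {
    thresholdBase <- match.arg(thresholdBase)
    if (thresholdFraction <= 0 || thresholdFraction >= 1)
      stop("thresholdFraction must be in (0, 1)", call. = FALSE)
    l <- x@layout
    inCluster <- !is.na(labels) & labels == cluster
    if (!any(inCluster))
      stop("cluster ", cluster, " is empty", call. = FALSE)
    base <- if (thresholdBase == "cluster") max(x@values[inCluster])
            else max(x@values[l@validMask])
    sel <- inCluster & x@values > thresholdFraction * base
    chanMask <- sel[cbind(l@row, l@col)]
    out <- l@channels[chanMask]
    if (length(out) == 0L) {
      # degenerate all-zero cluster: keep the contract that the peak channel
      # is always returned
      peak <- which(inCluster & x@values == max(x@values[inCluster]))
      keep <- l@row + (l@col - 1L) * nrow(x@values)
      out <- l@channels[keep %in% peak][1]
    }
    out
  })

#' Barycenter of a set of channels
#'
#' Coordinate mean (optionally amplitude-weighted) of the channel positions,
#' in mm in the grid frame; the estimate of the active region's position.
#'
#' @param layout a [GridLayout-class].
#' @param channels channel identifiers (at least one).
#' @param map raw [AmplitudeMap-class]; required for amplitude weighting.
#' @param weighting \code{"unweighted"} (default) or \code{"amplitude"}.
#' @return named numeric c(x_mm, y_mm).
#' @export
mapBarycenter <- function(layout, channels, map = NULL,
                          weighting = c("unweighted", "amplitude")) {
  weighting <- match.arg(weighting)
  if (length(channels) == 0L)
    stop("empty channel set", call. = FALSE)
  pos <- channelPosition(layout, channels)
  if (weighting == "unweighted") {
    w <- rep(1, length(channels))
  } else {
    if (is.null(map)) stop("amplitude weighting needs the map", call. = FALSE)
    w <- mapValues(map, "channels")[channels]
    if (sum(w) == 0) w <- rep(1, length(channels))
  }
  c(x_mm = sum(w * pos[, 1]) / sum(w), y_mm = sum(w * pos[, 2]) / sum(w))
}

#' Normalize a barycenter by the subject's forearm anatomy
#'
#' Converts the mm-frame barycenter into dimensionless anatomical
#' coordinates comparable across subjects: \code{X = x / circumference}
#' (medio-lateral, as a fraction of the proximal forearm circumference) and
#' \code{Y = y / length} (proximal-distal, as a fraction of the forearm
#' length, lateral epicondyle to ulnar styloid).
#'
#' @param baryMm numeric c(x_mm, y_mm).
#' @param forearmLengthMm forearm length in mm (> 0).
#' @param circumferenceMm proximal forearm circumference in mm (> 0).
#' @return named numeric c(X, Y).
#' @examples
#' normalizeBarycenter(c(25.5, 50.4), 252, 255)  # (0.1, 0.2)
#' @export
normalizeBarycenter <- function(baryMm, forearmLengthMm, circumferenceMm) {
  if (!is.finite(forearmLengthMm) || forearmLengthMm <= 0 ||
      !is.finite(circumferenceMm) || circumferenceMm <= 0)
    stop("anatomy measures must be positive", call. = FALSE)
  c(X = unname(baryMm[1]) / circumferenceMm,
    Y = unname(baryMm[2]) / forearmLengthMm)
}
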