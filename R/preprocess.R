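#' Zero-phase band-pass filtering of a grid recording
#'
#' Applies a 4th-order Butterworth band-pass (default 10-400 Hz, the
#' conditioning band for surface EMG) forward and backward
#' (\code{signal::filtfilt}) to every channel, so the filter is zero-phase and
#' epochs are not shifted in time. Sample count and channel count are
#' preserved; the band is recorded in the recording metadata.
#'
#' @param recording an [EMGRecording-class].
#' @param band numeric c(low, high) in Hz; must lie below the Nyquist
#'   frequency.
#' @return the filtered [EMGRecording-class].
#' @export
bandpassFilter <- function(recording, band = c(10, 400)) {
  fs <- samplingRate(recording)
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1] ||
      band[2] >= fs / 2)
    stop("band must satisfy 0 < low < high < fs/2", call. = FALSE)
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  data <- emgSignals(recording)
  for (j in seq_len(ncol(data)))
    data[, j] <- signal::filtfilt(bf, data[, j])
  out <- .replaceEmg(recording, data)
  metadata(out)$band <- band
  out
}

#' Automatic bad-channel detection
#'
#' Deterministic surrogate for visual quality assessment of raw signals.
#' A channel is flagged when it is flat (variance below \code{flatRel} times
#' the median channel variance), saturated (more than \code{satFraction} of
#' its samples sit at its amplitude rails) or an amplitude outlier (RMS both
#' more than \code{outlierK} robust SDs above the median channel RMS and more
#' than \code{neighborRatio} times the largest RMS among its 4-connected
#' neighbours). The spatial-isolation condition is what distinguishes a bad
#' contact from the genuine amplitude peak above an active muscle: a real
#' source elevates a whole neighbourhood, a bad contact only itself.
#'
#' @param recording an [EMGRecording-class].
#' @param flatRel flat threshold relative to median channel variance.
#' @param satFraction maximal tolerated fraction of rail samples.
#' @param outlierK robust-SD multiple for the outlier rule.
#' @param neighborRatio RMS ratio over the strongest neighbour for the
#'   outlier rule.
#' @return character vector of flagged channel identifiers (possibly empty).
#' @export
detectBadChannels <- function(recording, flatRel = 1e-12,
                              satFraction = 0.01, outlierK = 8,
                              neighborRatio = 3) {
  data <- emgSignals(recording)
  channels <- gridChannels(recordingLayout(recording))
  v <- apply(data, 2, stats::var)
  rms <- sqrt(colMeans(data^2))
  flat <- v <= flatRel * stats::median(v)

  railFrac <- vapply(seq_len(ncol(data)), function(j) {
    x <- data[, j]
    rng <- range(x)
    tol <- 1e-9 * max(diff(rng), abs(rng), 1e-300)
    mean(x >= rng[2] - tol | x <= rng[1] + tol)
  }, numeric(1))
  saturated <- railFrac > satFraction & !flat

  medRms <- stats::median(rms)
  robustSd <- stats::mad(rms)
  layout <- recordingLayout(recording)
  nbMax <- vapply(channels, function(ch) {
    nb <- gridNeighbors(layout, ch, connectivity = 4)
    if (length(nb) == 0L) medRms else max(rms[match(nb, channels)])
  }, numeric(1))
  outlier <- rms > medRms + outlierK * robustSd & rms > neighborRatio * nbMax

  channels[flat | saturated | outlier]
}

#' Replace bad channels by neighbour interpolation
#'
#' Each bad channel's signal is replaced, sample by sample, with the
#' unweighted mean of its valid 4-connected grid neighbours' signals. Bad
#' channels are excluded from each other's neighbour sets, and every bad
#' channel must keep at least one clean neighbour (the procedure targets the
#' isolated bad contacts typical of grid recordings; cascaded repair is not
#' attempted).
#'
#' @param recording an [EMGRecording-class].
#' @param bad character vector of channel identifiers to repair.
#' @return the repaired [EMGRecording-class]; its metadata records the
#'   repaired channels under \code{metadata()$repairedChannels}.
#' @export
replaceBadChannels <- function(recording, bad) {
  if (length(bad) == 0L) return(recording)
  layout <- recordingLayout(recording)
  .channelIndex(layout, bad)  # validates
  data <- emgSignals(recording)
  orig <- data
  for (ch in bad) {
    nb <- setdiff(gridNeighbors(layout, ch, connectivity = 4), bad)
    if (length(nb) == 0L)
      stop("channel ", ch, " has no clean neighbour to interpolate from",
           call. = FALSE)
    j <- .channelIndex(layout, ch)
    nbi <- .channelIndex(layout, nb)
    data[, j] <- rowMeans(orig[, nbi, drop = FALSE])
  }
  out <- .replaceEmg(recording, data)
  metadata(out)$repairedChannels <-
    union(metadata(out)$repairedChannels, bad)
  out
}

#' Select the analysis epoch of a recording
#'
#' In \code{"force"} mode, returns the epoch of length \code{epochS} whose
#' force signal has the smallest standard deviation over a sliding window
#' stepped one sample at a time (the steadiest-force epoch); ties are broken
#' toward the earliest window. In \code{"central"} mode (for contractions
#' without force tracking), returns the centred window.
#'
#' @param recording an [EMGRecording-class].
#' @param epochS epoch length in s (default 3).
#' @param mode \code{"force"} or \code{"central"}.
#' @return an [EpochWindow-class].
#' @export
selectEpoch <- function(recording, epochS = 3, mode = c("force", "central")) {
  mode <- match.arg(mode)
  fs <- samplingRate(recording)
  n <- nSamples(recording)
  w <- round(epochS * fs)
  if (w < 2L || w > n)
    stop("recording shorter than the requested epoch", call. = FALSE)
  if (mode == "central") {
    start <- (n - w) %/% 2L + 1L
    return(new("EpochWindow", startSample = as.integer(start),
               endSample = as.integer(start + w), mode = "central",
               criterionValue = NA_real_))
  }
  f <- forceSignal(recording)
  if (is.null(f))
    stop("steadiest-force epoch selection requires a force channel",
         call. = FALSE)
  f <- as.numeric(f) - mean(f)  # centring improves the running-sum precision
  s1 <- c(0, cumsum(f))
  s2 <- c(0, cumsum(f^2))
  starts <- seq_len(n - w + 1L)
  S1 <- s1[starts + w] - s1[starts]
  S2 <- s2[starts + w] - s2[starts]
  v <- pmax((S2 - S1^2 / w) / (w - 1), 0)
  best <- which(v <= min(v) + 1e-9 * (min(v) + 1e-300))[1]
  new("EpochWindow", startSample = as.integer(best),
      endSample = as.integer(best + w), mode = "force",
      criterionValue = sqrt(v[best]))
}
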