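#' Specify a synthetic spatially localized EMG source
#'
#' A source is a band-limited, zero-mean stochastic carrier whose amplitude is
#' projected onto the grid through an isotropic 2-D Gaussian spatial profile
#' centred at the ground-truth position: channel weight
#' \code{w = exp(-d^2 / (2 * spreadMm^2))} with \code{d} the channel-to-centre
#' distance. This reproduces the single compact amplitude peak that monopolar
#' maps show above a muscle's main innervation zone, which is all the
#' RMS-map analysis consumes; no motor-unit action-potential trains are
#' modelled.
#'
#' @param centerMm numeric c(x, y), ground-truth centre in the grid frame (mm).
#' @param spreadMm spatial standard deviation of the Gaussian profile in mm.
#'   The default 15 mm gives a 70%-amplitude footprint about 25 mm across,
#'   consistent with active regions a few centimetres long.
#' @param rmsAmplitude source RMS in signal units at its centre.
#' @param band c(low, high) Hz of the carrier's pass band.
#' @return a validated source specification (list).
#' @export
sourceSpec <- function(centerMm, spreadMm = 15, rmsAmplitude = 1,
                       band = c(20, 350)) {
  stopifnot(length(centerMm) == 2, all(is.finite(centerMm)))
  if (!is.finite(spreadMm) || spreadMm <= 0)
    stop("spreadMm must be > 0", call. = FALSE)
  if (!is.finite(rmsAmplitude) || rmsAmplitude < 0)
    stop("rmsAmplitude must be >= 0", call. = FALSE)
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1])
    stop("band must be c(low, high) with 0 < low < high", call. = FALSE)
  list(centerMm = as.numeric(centerMm), spreadMm = spreadMm,
       rmsAmplitude = rmsAmplitude, band = as.numeric(band))
}

# Band-limited zero-mean carrier with exact sample RMS `a`.
.bandCarrier <- function(n, fs, band, a) {
  e <- stats::rnorm(n)
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  e <- signal::filtfilt(bf, e)
  e <- e - mean(e)
  r <- sqrt(mean(e^2))
  if (r > 0 && a > 0) e * (a / r) else e * 0
}

#' Simulate a grid EMG recording with known ground truth
#'
#' Each channel records the weighted sum of the source carriers plus
#' independent white Gaussian noise:
#' \code{x_ch(t) = sum_s w_s(ch) e_s(t) + n(t)} with \code{w_s} the Gaussian
#' spatial weight of [sourceSpec()]. Carriers of distinct sources are
#' independent. The expected channel RMS is
#' \code{sqrt(sum_s w_s^2 a_s^2 + noiseRms^2)}. Output is bit-reproducible for
#' a fixed \code{seed}; the ground truth travels with the recording.
#'
#' @param layout a [GridLayout-class].
#' @param sources list of [sourceSpec()] specifications (may be empty).
#' @param noiseRms per-channel additive white-noise RMS (signal units).
#' @param durationS recording length in s.
#' @param fs sampling rate in samples/s (default 2048).
#' @param force optional per-sample force signal, e.g. from [simulateForce()].
#' @param meta metadata list passed to [EMGRecording()].
#' @param seed integer seed; all randomness derives from it.
#' @return an [EMGRecording-class] whose \code{metadata()$groundTruth} records
#'   sources, noise RMS and seed.
#' @examples
#' layout <- buildGrid(gridSpec(5, 5, 10))
#' rec <- simulateRecording(layout, list(sourceSpec(c(20, 20))),
#'                          noiseRms = 0.1, durationS = 1, fs = 512, seed = 1)
#' @export
simulateRecording <- function(layout, sources = list(), noiseRms = 0,
                              durationS, fs = 2048, force = NULL,
                              meta = list(), seed = NULL) {
  if (!is.finite(durationS) || durationS <= 0)
    stop("durationS must be > 0", call. = FALSE)
  if (!is.finite(noiseRms) || noiseRms < 0)
    stop("noiseRms must be >= 0", call. = FALSE)
  for (s in sources)
    if (s$band[2] >= fs / 2)
      stop("source band must lie below the Nyquist frequency", call. = FALSE)
  n <- round(durationS * fs)
  nch <- nChannels(layout)
  gen <- function() {
    data <- matrix(0, n, nch)
    for (s in sources) {
      d2 <- (layout@x - s$centerMm[1])^2 + (layout@y - s$centerMm[2])^2
      w <- exp(-d2 / (2 * s$spreadMm^2))
      e <- .bandCarrier(n, fs, s$band, s$rmsAmplitude)
      data <- data + outer(e, w)
    }
    if (noiseRms > 0)
      data <- data + matrix(stats::rnorm(n * nch, sd = noiseRms), n, nch)
    data
  }
  data <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  EMGRecording(data, layout, fs, force = force, meta = meta,
               groundTruth = list(
                 sources = sources, noiseRms = noiseRms,
                 badChannels = character(), seed = seed))
}

#' Simulate an isometric contraction force trace
#'
#' Linear ramp up, held plateau, linear ramp down, with optional additive
#' white noise over the whole trace. The plateau sample range is attached as
#' attributes \code{plateauStart} / \code{plateauEnd} (half-open, 1-based) for
#' ground-truth checks of steadiest-force epoch selection.
#'
#' @param plateauLevel force at the plateau (e.g. %MVC).
#' @param durationS total duration in s.
#' @param fs sampling rate in samples/s.
#' @param rampS up/down ramp duration in s; requires \code{2 * rampS <
#'   durationS}.
#' @param noiseRms force noise RMS.
#' @param seed integer seed.
#' @return numeric force vector of length \code{round(durationS * fs)}.
#' @export
simulateForce <- function(plateauLevel, durationS, fs, rampS = 0.5,
                          noiseRms = 0, seed = NULL) {
  if (!is.finite(durationS) || durationS <= 0 || !is.finite(rampS) ||
      rampS < 0 || 2 * rampS >= durationS)
    stop("need 0 <= 2 * rampS < durationS", call. = FALSE)
  if (!is.finite(noiseRms) || noiseRms < 0)
    stop("noiseRms must be >= 0", call. = FALSE)
  n <- round(durationS * fs)
  nr <- round(rampS * fs)
  f <- rep(plateauLevel, n)
  if (nr > 0) {
    f[seq_len(nr)] <- plateauLevel * (seq_len(nr) - 1) / nr
    f[n - seq_len(nr) + 1] <- plateauLevel * (seq_len(nr) - 1) / nr
  }
  if (noiseRms > 0) {
    addNoise <- function() f + stats::rnorm(n, sd = noiseRms)
    f <- if (is.null(seed)) addNoise() else withr::with_seed(seed, addNoise())
  }
  attr(f, "plateauStart") <- nr + 1L
  attr(f, "plateauEnd") <- n - nr + 1L
  f
}

#' Inject bad channels into a recording
#'
#' Emulates bad skin-electrode contact: the listed channels are replaced by a
#' flat signal, a clipped (saturated) copy of the original, or high-amplitude
#' white noise. All other channels are untouched. The injected identifiers are
#' appended to the recording's ground truth.
#'
#' @param recording an [EMGRecording-class].
#' @param channels channel identifiers to corrupt (may be empty).
#' @param mode \code{"flat"}, \code{"saturated"} or \code{"noisy"}.
#' @param noisyFactor noisy-mode RMS as a multiple of the recording's median
#'   channel RMS (default 20).
#' @param clipFraction saturated-mode clip level as a fraction of the
#'   channel's peak absolute amplitude (default 0.5).
#' @param seed integer seed (noisy mode only).
#' @return a modified [EMGRecording-class].
#' @export
injectBadChannels <- function(recording, channels,
                              mode = c("flat", "saturated", "noisy"),
                              noisyFactor = 20, clipFraction = 0.5,
                              seed = NULL) {
  mode <- match.arg(mode)
  if (length(channels) == 0L) return(recording)
  layout <- recordingLayout(recording)
  i <- .channelIndex(layout, channels)
  data <- emgSignals(recording)
  if (mode == "flat") {
    data[, i] <- 0
  } else if (mode == "saturated") {
    for (j in i) {
      rail <- clipFraction * max(abs(data[, j]))
      data[, j] <- pmin(pmax(data[, j], -rail), rail)
    }
  } else {
    rmsAll <- sqrt(colMeans(data^2))
    target <- noisyFactor * stats::median(rmsAll)
    gen <- function() matrix(stats::rnorm(nrow(data) * length(i), sd = target),
                             nrow(data), length(i))
    data[, i] <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  }
  out <- .replaceEmg(recording, data)
  gt <- metadata(out)$groundTruth
  if (is.null(gt)) gt <- list(badChannels = character())
  gt$badChannels <- union(gt$badChannels, channels)
  metadata(out)$groundTruth <- gt
  out
}
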