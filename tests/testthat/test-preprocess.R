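makeRec <- function(data, fs, layout = NULL, force = NULL) {
  if (is.null(layout))
    layout <- buildGrid(gridSpec(1, ncol(as.matrix(data)), 10))
  EMGRecording(as.matrix(data), layout, fs, force = force)
}

test_that("band-pass filtering passes the band and rejects outside it", {
  fs <- 2048
  t <- seq(0, 3 - 1/fs, by = 1/fs)
  trim <- (0.25 * fs):((3 - 0.25) * fs)  # discard filter edges

  dc <- makeRec(cbind(rep(2, length(t))), fs)
  out <- emgSignals(bandpassFilter(dc, c(10, 400)))[, 1]
  expect_lt(sqrt(mean(out[trim]^2)), 0.01 * 2)

  s100 <- makeRec(cbind(sin(2 * pi * 100 * t)), fs)
  out <- emgSignals(bandpassFilter(s100, c(10, 400)))[, 1]
  amp <- sqrt(2) * sqrt(mean(out[trim]^2))
  expect_lt(abs(amp - 1), 0.05)

  s800 <- makeRec(cbind(sin(2 * pi * 800 * t)), fs)
  out <- emgSignals(bandpassFilter(s800, c(10, 400)))[, 1]
  expect_lt(sqrt(mean(out[trim]^2)), 0.1 * sqrt(0.5))
})

test_that("filtering preserves shape and validates the band", {
  l <- tinyLayout(3)
  rec <- simulateRecording(l, noiseRms = 1, durationS = 1, fs = 512, seed = 1)
  out <- bandpassFilter(rec, c(10, 200))
  expect_equal(dim(emgSignals(out)), dim(emgSignals(rec)))
  expect_error(bandpassFilter(rec, c(10, 300)), "fs/2")
  expect_error(bandpassFilter(rec, c(100, 50)), "band")
})

test_that("bad-channel detection flags exactly the corrupted channels", {
  l <- tinyLayout(5)
  clean <- simulateRecording(l, list(sourceSpec(c(20, 20), spreadMm = 12)),
                             noiseRms = 0.3, durationS = 2, fs = 1024,
                             seed = 8)
  expect_identical(detectBadChannels(clean), character(0))

  flat <- injectBadChannels(clean, "r04c02", "flat")
  expect_identical(detectBadChannels(flat), "r04c02")

  noisy <- injectBadChannels(clean, "r01c05", "noisy", seed = 9)
  expect_identical(detectBadChannels(noisy), "r01c05")
})

test_that("bad channels are replaced by the mean of clean 4-neighbours", {
  fs <- 256
  t <- seq_len(fs) / fs
  s <- sin(2 * pi * 5 * t)

  # corner channel of a 2x2 grid has exactly two neighbours: 2s and 4s
  l2 <- buildGrid(gridSpec(2, 2, 10))
  data <- cbind(99 * s, 2 * s, 4 * s, 0 * s)  # r01c01, r01c02, r02c01, r02c02
  rec <- makeRec(data, fs, layout = l2)
  rep1 <- replaceBadChannels(rec, "r01c01")
  expect_equal(emgSignals(rep1)[, "r01c01"], 3 * s)

  # identical neighbours reproduce the signal exactly
  l3 <- buildGrid(gridSpec(3, 3, 10))
  data <- matrix(rep(s, 9), ncol = 9)
  data[, 5] <- 0  # r02c02, the centre
  rec <- makeRec(data, fs, layout = l3)
  expect_equal(emgSignals(replaceBadChannels(rec, "r02c02"))[, "r02c02"], s)

  # random recording: sample-wise brute-force oracle
  l5 <- tinyLayout(5)
  rec <- simulateRecording(l5, noiseRms = 1, durationS = 0.5, fs = 256,
                           seed = 10)
  bad <- "r03c03"
  fixed <- replaceBadChannels(rec, bad)
  nb <- gridNeighbors(l5, bad, 4)
  oracle <- rowMeans(emgSignals(rec)[, nb])
  expect_equal(emgSignals(fixed)[, bad], oracle)

  # untouched elsewhere, and idempotent for a fixed bad set
  other <- setdiff(gridChannels(l5), bad)
  expect_identical(emgSignals(fixed)[, other], emgSignals(rec)[, other])
  expect_identical(emgSignals(replaceBadChannels(fixed, bad)),
                   emgSignals(fixed))

  # isolated-repair precondition: all neighbours bad -> unrecoverable
  expect_error(replaceBadChannels(rec, c("r03c03", gridNeighbors(l5, "r03c03", 4))),
               "no clean neighbour")
})

test_that("steadiest-force epoch selection matches exhaustive search", {
  fs <- 64
  l <- buildGrid(gridSpec(1, 1, 10))
  set.seed(31)
  for (rep in 1:5) {
    f <- simulateForce(20, 10, fs, rampS = 1, noiseRms = 0.4,
                       seed = 40 + rep)
    rec <- makeRec(cbind(rnorm(length(f))), fs, layout = l, force = f)
    w <- 3 * fs
    sds <- vapply(seq_len(length(f) - w + 1),
                  function(i) sd(f[i:(i + w - 1)]), numeric(1))
    ep <- selectEpoch(rec, 3, "force")
    expect_equal(ep@startSample, which.min(sds))
    expect_equal(ep@endSample - ep@startSample, w)
    expect_equal(ep@criterionValue, min(sds), tolerance = 1e-8)
  }
})

test_that("epoch selection handles plateaus, ramps, central mode and errors", {
  fs <- 128
  l <- buildGrid(gridSpec(1, 1, 10))
  f <- simulateForce(20, 8, fs, rampS = 1, noiseRms = 0)
  rec <- makeRec(cbind(rnorm(length(f))), fs, layout = l, force = f)
  ep <- selectEpoch(rec, 3, "force")
  expect_gte(ep@startSample, attr(f, "plateauStart"))
  expect_lte(ep@endSample, attr(f, "plateauEnd"))
  expect_equal(ep@criterionValue, 0)

  # strictly linear ramp: every window ties; earliest returned
  ramp <- seq(0, 10, length.out = 8 * fs)
  rec <- makeRec(cbind(rnorm(length(ramp))), fs, layout = l, force = ramp)
  expect_equal(selectEpoch(rec, 3, "force")@startSample, 1L)

  # central mode on a 5 s recording -> [1 s, 4 s)
  rec5 <- makeRec(cbind(rnorm(5 * fs)), fs, layout = l)
  ep <- selectEpoch(rec5, 3, "central")
  expect_equal(ep@startSample, fs + 1L)
  expect_equal(ep@endSample, 4L * fs + 1L)

  expect_error(selectEpoch(rec5, 3, "force"), "force channel")
  expect_error(selectEpoch(rec5, 6, "central"), "shorter")
})
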