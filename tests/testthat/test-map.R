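test_that("RMS maps implement the definition", {
  fs <- 512
  l <- buildGrid(gridSpec(1, 3, 10))
  t <- seq_len(2 * fs) / fs
  data <- cbind(rep(-3, length(t)),          # constant
                sin(2 * pi * 8 * t),         # whole periods in any 1 s window
                rep(0, length(t)))
  rec <- EMGRecording(data, l, fs)
  m <- computeRmsMap(rec)
  v <- mapValues(m, "channels")
  expect_equal(unname(v[1]), 3)
  expect_equal(unname(v[2]), 1 / sqrt(2), tolerance = 1e-3)
  expect_equal(unname(v[3]), 0)

  zero <- computeRmsMap(EMGRecording(matrix(0, 100, 3), l, fs))
  expect_true(all(mapValues(zero, "channels") == 0))

  ep <- new("EpochWindow", startSample = 1L, endSample = 9999L,
            mode = "central", criterionValue = NA_real_)
  expect_error(computeRmsMap(rec, ep), "exceeds")
})

test_that("rank equalization maps onto [0,1], preserving order and ties", {
  std <- buildGrid(standardSpec())
  set.seed(41)
  vals <- runif(128)
  eq <- equalizeMap(valueMap(std, vals))
  e <- mapValues(eq, "channels")
  expect_equal(min(e), 0)
  expect_equal(max(e), 1)
  # explicit sort-based oracle for distinct values: (rank-1)/127
  expect_equal(unname(e), (rank(vals) - 1) / 127)
  # monotone: a < b => eq(a) < eq(b)
  ord <- order(vals)
  expect_true(all(diff(e[ord]) > 0))

  # ties share a value
  vals2 <- c(rep(0.5, 64), runif(64, 0.6, 1))
  e2 <- mapValues(equalizeMap(valueMap(std, vals2)), "channels")
  expect_length(unique(e2[1:64]), 1L)

  expect_warning(equalizeMap(valueMap(std, rep(1, 128))), "constant")
})

test_that("watershed segmentation separates blobs and labels every cell", {
  std <- buildGrid(standardSpec())

  one <- equalizeMap(blobMap(std, list(c(20, 60)), 1, spread = 15))
  lab1 <- segmentMap(one)
  expect_equal(max(lab1, na.rm = TRUE), 1L)

  # two blobs 60 mm apart, spread 10 mm -> two clusters holding their peaks
  two <- blobMap(std, list(c(10, 20), c(10, 80)), c(1, 0.8), spread = 10)
  lab2 <- segmentMap(equalizeMap(two))
  expect_equal(max(lab2, na.rm = TRUE), 2L)
  peakA <- which(two@values == max(two@values[std@validMask]), arr.ind = TRUE)
  expect_false(is.na(lab2[peakA]))
  labA <- lab2[peakA]
  vB <- two@values
  vB[!is.na(lab2) & lab2 == labA] <- NA
  peakB <- which(vB == max(vB, na.rm = TRUE), arr.ind = TRUE)[1, , drop = FALSE]
  expect_false(lab2[peakB] == labA)

  # labels partition the valid cells: invalid NA, valid labelled exactly once
  expect_true(all(!is.na(lab2[std@validMask])))
  expect_true(all(is.na(lab2[!std@validMask])))

  # constant map degenerates to a single cluster
  suppressWarnings({
    labc <- segmentMap(equalizeMap(valueMap(std, rep(2, 128))))
  })
  expect_equal(max(labc, na.rm = TRUE), 1L)
})

test_that("segmentation agrees with an independent watershed implementation", {
  skip_if_not_installed("EBImage")
  full <- buildGrid(gridSpec(12, 12, 10))
  m <- blobMap(full, list(c(20, 20), c(60, 90)), c(1, 0.7), spread = 12)
  eq <- equalizeMap(m)
  mine <- segmentMap(eq, 8)
  ref <- t(EBImage::imageData(EBImage::watershed(
    EBImage::Image(t(mapValues(eq))), tolerance = 1e-9, ext = 1)))
  expect_equal(max(mine, na.rm = TRUE), max(ref))
  # same partition up to label permutation, modulo EBImage's watershed-line
  # cells (label 0) and a handful of saddle cells whose basin assignment is
  # implementation-defined
  tab <- table(mine, ref[, ])
  tab <- tab[, colnames(tab) != "0", drop = FALSE]
  agree <- sum(apply(tab, 1, max))
  expect_gte(agree / sum(tab), 0.95)
  # each implementation puts the two blob peaks in different clusters
  for (lb in list(mine, ref)) {
    expect_false(lb[3, 5] == lb[10, 9])  # cells nearest the two centres
  }
})

test_that("primary-cluster selection takes the highest raw peak", {
  l <- buildGrid(gridSpec(1, 6, 10))
  map <- valueMap(l, c(1.0, 0.2, 0.1, 0.2, 0.6, 0.3))
  labels <- matrix(c(1L, 1L, 1L, 2L, 2L, 2L), 1, 6)
  expect_equal(selectPrimaryCluster(labels, map), 1L)

  map2 <- valueMap(l, c(0.6, 0.2, 0.1, 0.2, 1.0, 0.3))
  expect_equal(selectPrimaryCluster(labels, map2), 2L)

  # exact tie -> lowest cluster id
  map3 <- valueMap(l, c(1.0, 0.2, 0.1, 0.2, 1.0, 0.3))
  expect_equal(selectPrimaryCluster(labels, map3), 1L)

  single <- matrix(1L, 1, 6)
  expect_equal(selectPrimaryCluster(single, map), 1L)
})

test_that("the 70% threshold is relative, per cluster, and strict", {
  l <- buildGrid(gridSpec(1, 5, 10))
  labels <- matrix(c(1L, 1L, 1L, 2L, 2L), 1, 5)
  map <- valueMap(l, c(1.0, 0.8, 0.69, 0.5, 0.2))
  expect_setequal(relevantChannels(map, labels = labels, cluster = 1),
                  c("r01c01", "r01c02"))
  # boundary: exactly 0.70 * max is excluded ("higher than" is strict)
  map2 <- valueMap(l, c(1.0, 0.7, 0.71, 0.5, 0.2))
  expect_setequal(relevantChannels(map2, labels = labels, cluster = 1),
                  c("r01c01", "r01c03"))
  # equal amplitudes a satisfy a > 0.7a for a > 0: all returned
  map3 <- valueMap(l, c(0.4, 0.4, 0.4, 0.5, 0.2))
  expect_setequal(relevantChannels(map3, labels = labels, cluster = 1),
                  c("r01c01", "r01c02", "r01c03"))
  # global-base variant references the whole-map maximum
  expect_setequal(relevantChannels(map, labels = labels, cluster = 2,
                                   thresholdBase = "global"),
                  "r01c04")
})

test_that("barycenters equal the coordinate mean (oracle) and support weights", {
  std <- buildGrid(standardSpec())
  one <- "r05c07"
  expect_equal(mapBarycenter(std, one),
               c(x_mm = unname(channelPosition(std, one)[1, 1]),
                 y_mm = unname(channelPosition(std, one)[1, 2])))

  # symmetric about the reference column -> x = 0
  expect_equal(unname(mapBarycenter(std, c("r05c02", "r05c04"))[1]), 0)

  set.seed(43)
  chans <- sample(gridChannels(std), 17)
  pos <- channelPosition(std, chans)
  expect_equal(mapBarycenter(std, chans),
               c(x_mm = sum(pos[, 1]) / 17, y_mm = sum(pos[, 2]) / 17))

  vals <- runif(128)
  map <- valueMap(std, vals)
  w <- mapValues(map, "channels")[chans]
  expect_equal(mapBarycenter(std, chans, map, "amplitude"),
               c(x_mm = sum(w * pos[, 1]) / sum(w),
                 y_mm = sum(w * pos[, 2]) / sum(w)))

  expect_error(mapBarycenter(std, character()), "empty")
})

test_that("anatomical normalization divides by circumference and length", {
  expect_equal(normalizeBarycenter(c(25.5, 50.4), 252, 255),
               c(X = 0.1, Y = 0.2))
  expect_equal(normalizeBarycenter(c(0, 0), 252, 255), c(X = 0, Y = 0))
  n1 <- normalizeBarycenter(c(30, 40), 250, 260)
  n2 <- normalizeBarycenter(c(30, 40), 500, 520)
  expect_equal(n2, n1 / 2)
  expect_error(normalizeBarycenter(c(1, 1), -5, 255), "positive")
})
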