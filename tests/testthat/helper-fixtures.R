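# Shared fixtures: tiny grids, analytic maps and hand-built results.

tinyLayout <- function(n = 5, pitch = 10, refCol = 1) {
  buildGrid(gridSpec(n, n, pitch, referenceCol = refCol))
}

standardSpec <- function() {
  gridSpec(12, 12, 10,
           missingBlocks = list(list(rows = c(1, 2), cols = c(1, 4)),
                                list(rows = c(11, 12), cols = c(1, 4))),
           referenceCol = 3)
}

# Analytic Gaussian-blob map on a layout (no simulation involved).
blobMap <- function(layout, centers, amps, spread = 10) {
  m <- matrix(NA_real_, layout@spec@nRows, layout@spec@nCols)
  v <- rep(0, nChannels(layout))
  for (k in seq_along(amps)) {
    d2 <- (layout@x - centers[[k]][1])^2 + (layout@y - centers[[k]][2])^2
    v <- v + amps[k] * exp(-d2 / (2 * spread^2))
  }
  m[cbind(layout@row, layout@col)] <- v
  new("AmplitudeMap", values = m, layout = layout, equalized = FALSE)
}

# Map with explicitly given channel values (layout channel order).
valueMap <- function(layout, values) {
  m <- matrix(NA_real_, layout@spec@nRows, layout@spec@nCols)
  m[cbind(layout@row, layout@col)] <- values
  new("AmplitudeMap", values = m, layout = layout, equalized = FALSE)
}

# Minimal LocalizationResult carrying only what the stats layer reads.
fakeResult <- function(subject, task, level, X, Y) {
  l <- buildGrid(gridSpec(1, 2, 10))
  map <- valueMap(l, c(1, 0.5))
  labels <- matrix(1L, 1, 2)
  new("LocalizationResult",
      ampMap = map, equalizedMap = map, labels = labels,
      primaryCluster = 1L, relevantChannels = "r01c01",
      barycenterMm = c(0, 0), barycenterNorm = c(X, Y),
      badChannels = character(),
      epoch = new("EpochWindow", startSample = 1L, endSample = 2L,
                  mode = "central", criterionValue = NA_real_),
      meta = list(subject = subject, task = task, levelPctMVC = level))
}

# Barycenter table simulated directly (no signal processing).
simulateTable <- function(nSubjects, taskMeansX, taskMeansY = NULL,
                          sd = 0.02) {
  tasks <- names(taskMeansX)
  if (is.null(taskMeansY)) taskMeansY <- setNames(rep(0, length(tasks)),
                                                  tasks)
  rows <- expand.grid(subject = sprintf("S%02d", seq_len(nSubjects)),
                      task = tasks, stringsAsFactors = FALSE)
  data.frame(subject = rows$subject, task = rows$task, level_pct_mvc = 20,
             X = taskMeansX[rows$task] + rnorm(nrow(rows), 0, sd),
             Y = taskMeansY[rows$task] + rnorm(nrow(rows), 0, sd),
             row.names = NULL)
}
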