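#' Default task set of the synthetic forearm study
#'
#' Seven isometric contraction tasks of the dorsal forearm with plausible
#' ground-truth source centres on the standard 128-electrode grid frame
#' (x from the reference column toward the radial side, y from the proximal
#' row distally, mm). The centres encode the anatomy the tasks target: the
#' two ECR heads share a medio-lateral position but sit ~45 mm apart
#' longitudinally (radial deviation proximal, wrist extension distal), and
#' the middle- and ring-finger EDC compartments share a medio-lateral
#' position ~22 mm apart longitudinally — so those two pairs should separate
#' on Y but not on X, while every pair is at least 20 mm apart on some axis.
#'
#' @return data.frame with columns \code{task}, \code{centerX}, \code{centerY},
#'   \code{tracked} (force-tracked at multiple %MVC levels or not).
#' @export
defaultTaskTable <- function() {
  data.frame(
    task = c("wrist_extension", "radial_deviation", "ulnar_deviation",
             "elbow_flexion", "middle_finger_extension",
             "ring_finger_extension", "little_finger_extension"),
    centerX = c(30, 30, -10, 70, 10, 10, -5),
    centerY = c(60, 15, 55, 20, 40, 62, 85),
    tracked = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
}

#' Design a synthetic grid-EMG study
#'
#' Lays out one recording per subject x task x force level, mirroring a
#' protocol with force-tracked wrist contractions (extension, radial and
#' ulnar deviation at 20/50/80 %MVC; 10 s at 20 and 50, 5 s at 80) and
#' untracked tasks (5 s, analyzed with a central epoch, nominal 20 %MVC).
#' Ground-truth source centres are the task centres plus a subject-specific
#' offset (SD \code{subjectSdMm}) shared across that subject's contractions
#' and a per-contraction jitter (SD \code{jitterSdMm}). Source amplitude
#' scales with the force level while the centre does not, so force level
#' shifts no barycenter by construction. Ring-finger extension carries a
#' weaker crosstalk source at the middle-finger centre. Subject anatomy is
#' drawn around cohort-typical values (forearm length 252 +/- 18 mm,
#' proximal circumference 255 +/- 22 mm).
#'
#' @param seed integer; every random quantity of the design derives from it.
#' @param nSubjects number of subjects (default 10).
#' @param taskTable task definition, see [defaultTaskTable()].
#' @param levels %MVC levels of the force-tracked tasks (default 20, 50, 80).
#' @param noiseRms channel noise RMS in units of the 20%-MVC source amplitude
#'   (default 0.25, i.e. power SNR 16 at the source centre at 20 %MVC).
#' @param subjectSdMm SD of the per-subject centre offset (default 3).
#' @param jitterSdMm SD of the per-contraction centre jitter (default 2).
#' @param spreadMm source spatial spread (default 15).
#' @param crosstalkAmp relative amplitude of the ring-finger crosstalk source
#'   (default 0.4; 0 disables it).
#' @return data.frame with one row per recording: subject, task, level,
#'   duration, tracked flag, ground-truth centre, amplitude, anatomy and the
#'   derived per-recording seed.
#' @export
syntheticStudyDesign <- function(seed, nSubjects = 10,
                                 taskTable = defaultTaskTable(),
                                 levels = c(20, 50, 80), noiseRms = 0.25,
                                 subjectSdMm = 3, jitterSdMm = 2,
                                 spreadMm = 15, crosstalkAmp = 0.4) {
  stopifnot(nSubjects >= 1)
  withr::with_seed(as.integer(seed), {
    subjects <- data.frame(
      subject = sprintf("S%02d", seq_len(nSubjects)),
      forearmLengthMm = stats::rnorm(nSubjects, 252, 18),
      forearmCircumferenceMm = stats::rnorm(nSubjects, 255, 22),
      offsetX = stats::rnorm(nSubjects, 0, subjectSdMm),
      offsetY = stats::rnorm(nSubjects, 0, subjectSdMm))
    rows <- list()
    for (si in seq_len(nSubjects)) {
      for (ti in seq_len(nrow(taskTable))) {
        lv <- if (taskTable$tracked[ti]) levels else 20
        for (level in lv) {
          duration <- if (taskTable$tracked[ti] && level < 80) 10 else 5
          rows[[length(rows) + 1L]] <- data.frame(
            subject = subjects$subject[si],
            task = taskTable$task[ti],
            level_pct_mvc = level,
            tracked = taskTable$tracked[ti],
            durationS = duration,
            sourceX = taskTable$centerX[ti] + subjects$offsetX[si] +
              stats::rnorm(1, 0, jitterSdMm),
            sourceY = taskTable$centerY[ti] + subjects$offsetY[si] +
              stats::rnorm(1, 0, jitterSdMm),
            amplitude = level / 20,
            spreadMm = spreadMm,
            noiseRms = noiseRms,
            crosstalkAmp = if (taskTable$task[ti] ==
                               "ring_finger_extension") crosstalkAmp else 0,
            forearmLengthMm = subjects$forearmLengthMm[si],
            forearmCircumferenceMm = subjects$forearmCircumferenceMm[si])
        }
      }
    }
    design <- do.call(rbind, rows)
    design$recSeed <- (as.integer(seed) %% 1000000L) * 1000L +
      seq_len(nrow(design))
    rownames(design) <- NULL
    design
  })
}

#' Simulate one recording of a synthetic study design
#'
#' @param design a design data.frame from [syntheticStudyDesign()].
#' @param i row index of the recording to simulate.
#' @param layout the [GridLayout-class] (default [standardGrid128()]).
#' @param fs sampling rate (default 2048).
#' @return an [EMGRecording-class], with a force channel for tracked tasks.
#' @export
simulateStudyRecording <- function(design, i, layout = standardGrid128(),
                                   fs = 2048) {
  d <- design[i, ]
  band <- c(20, min(350, 0.45 * fs))  # keep the carrier below Nyquist
  sources <- list(sourceSpec(c(d$sourceX, d$sourceY), spreadMm = d$spreadMm,
                             rmsAmplitude = d$amplitude, band = band))
  if (d$crosstalkAmp > 0) {
    tt <- defaultTaskTable()
    mid <- tt[tt$task == "middle_finger_extension", ]
    sources <- c(sources, list(
      sourceSpec(c(mid$centerX, mid$centerY), spreadMm = d$spreadMm,
                 rmsAmplitude = d$amplitude * d$crosstalkAmp, band = band)))
  }
  force <- NULL
  if (d$tracked)
    force <- simulateForce(d$level_pct_mvc, d$durationS, fs, rampS = 1,
                           noiseRms = 0.02 * d$level_pct_mvc,
                           seed = d$recSeed + 500000000L)
  simulateRecording(layout, sources, noiseRms = d$noiseRms,
                    durationS = d$durationS, fs = fs, force = force,
                    meta = list(subject = d$subject, task = d$task,
                                levelPctMVC = d$level_pct_mvc,
                                forearmLengthMm = d$forearmLengthMm,
                                forearmCircumferenceMm =
                                  d$forearmCircumferenceMm),
                    seed = d$recSeed)
}

#' Run a synthetic study end to end in memory
#'
#' Simulates and localizes every recording of the design one at a time
#' (recordings are discarded after localization, so memory stays flat) and
#' aggregates the normalized barycenters.
#'
#' @inheritParams simulateStudyRecording
#' @param ... further arguments passed to [localize()].
#' @return list with \code{table} (the barycenter table) and \code{details}
#'   (per-recording ground truth, recovered barycenter in mm and the
#'   localization error in mm).
#' @export
runStudy <- function(design, layout = standardGrid128(), fs = 2048, ...) {
  results <- vector("list", nrow(design))
  err <- bx <- by <- extX <- extY <- numeric(nrow(design))
  for (i in seq_len(nrow(design))) {
    rec <- simulateStudyRecording(design, i, layout = layout, fs = fs)
    res <- localize(rec, ...)
    results[[i]] <- res
    bx[i] <- res@barycenterMm[1]
    by[i] <- res@barycenterMm[2]
    err[i] <- sqrt((bx[i] - design$sourceX[i])^2 +
                   (by[i] - design$sourceY[i])^2)
    # footprint of the active region: span of the relevant channels plus one
    # electrode pitch (each electrode stands for a pitch-wide cell)
    pos <- channelPosition(layout, relevantChannels(res))
    extX[i] <- diff(range(pos[, "x_mm"])) + pitchMm(layout)
    extY[i] <- diff(range(pos[, "y_mm"])) + pitchMm(layout)
  }
  details <- cbind(design[, c("subject", "task", "level_pct_mvc",
                              "sourceX", "sourceY")],
                   data.frame(baryX = bx, baryY = by, errorMm = err,
                              extentXMm = extX, extentYMm = extY))
  list(table = buildBarycenterTable(results), details = details)
}

#' Write a synthetic study to disk as CSV recordings plus a manifest
#'
#' Each recording is written with [writeRecordingCsv()]; the manifest JSON
#' lists the recording files and echoes the full design (ground truth
#' included), making the study folder self-describing and re-runnable with
#' [runPipeline()].
#'
#' @inheritParams simulateStudyRecording
#' @param outDir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
generateSyntheticStudy <- function(design, outDir,
                                   layout = standardGrid128(), fs = 2048) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  files <- character(nrow(design))
  for (i in seq_len(nrow(design))) {
    rec <- simulateStudyRecording(design, i, layout = layout, fs = fs)
    files[i] <- sprintf("%s_%s_%03d.csv", design$subject[i],
                        design$task[i], round(design$level_pct_mvc[i]))
    writeRecordingCsv(rec, file.path(outDir, files[i]))
  }
  manifest <- file.path(outDir, "manifest.json")
  jsonlite::write_json(list(recordings = files, design = design),
                       manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Run the localization + statistics pipeline over a recording manifest
#'
#' Reads every recording listed in the manifest, localizes it, and writes per
#' recording a result JSON and amplitude/label map CSVs; then aggregates the
#' barycenter table (TSV) and, when the table holds a balanced single-level
#' design with at least two tasks, the two-way ANOVA and pairwise
#' discrimination reports. A failing recording is logged and skipped; the
#' returned summary (and its \code{status} field) reports partial success.
#' All artifacts embed the configuration they were produced under; the run
#' log (timings) is the only non-deterministic output.
#'
#' @param manifest path to a manifest JSON (\code{recordings}: file names
#'   relative to the manifest's directory).
#' @param outDir output directory.
#' @param alpha significance level for the discrimination report.
#' @param ... further arguments passed to [localize()].
#' @return invisibly, a list: \code{nOk}, \code{nFailed}, \code{failures},
#'   \code{status} (0 = all succeeded, 1 = partial), \code{table}.
#' @export
runPipeline <- function(manifest, outDir, alpha = 0.05, ...) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  m <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  base <- dirname(manifest)
  cfg <- list(alpha = alpha, localize = list(...))
  jsonlite::write_json(cfg, file.path(outDir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log <- file.path(outDir, "run.log")
  cat(sprintf("pipeline start; %d recording(s)\n", length(m$recordings)),
      file = log)
  results <- list()
  failures <- character()
  for (f in m$recordings) {
    t0 <- proc.time()[3]
    res <- tryCatch({
      rec <- readRecordingCsv(file.path(base, f))
      localize(rec, ...)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, f)
      cat(sprintf("FAIL %s: %s\n", f, conditionMessage(res)),
          file = log, append = TRUE)
      next
    }
    stem <- sub("\\.csv$", "", f)
    writeLocalizationJson(res, file.path(outDir,
                                         paste0(stem, ".result.json")))
    writeMapCsv(mapValues(res@ampMap), file.path(outDir,
                                                 paste0(stem, ".amp.csv")))
    writeMapCsv(clusterLabels(res), file.path(outDir,
                                              paste0(stem, ".labels.csv")))
    if (length(res@badChannels))
      cat(sprintf("WARN %s: repaired %d bad channel(s): %s\n", f,
                  length(res@badChannels),
                  paste(res@badChannels, collapse = ", ")),
          file = log, append = TRUE)
    cat(sprintf("OK %s (%.2fs)\n", f, proc.time()[3] - t0),
        file = log, append = TRUE)
    results[[length(results) + 1L]] <- res
  }
  table <- tryCatch(buildBarycenterTable(results), error = function(e) NULL)
  if (!is.null(table) && nrow(table)) {
    utils::write.table(table, file.path(outDir, "barycenters.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    statsOk <- length(unique(table$task)) >= 2 &&
      length(unique(table$level_pct_mvc)) == 1 &&
      !anyDuplicated(paste(table$subject, table$task)) &&
      length(unique(table$subject)) >= 2
    if (statsOk) tryCatch({
      for (axis in c("X", "Y"))
        utils::write.table(twowayAnova(table, axis),
                           file.path(outDir, sprintf("anova_%s.tsv", axis)),
                           sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(pairwiseDiscrimination(table, alpha = alpha),
                         file.path(outDir, "pairwise.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }, error = function(e)
      cat(sprintf("WARN stats skipped: %s\n", conditionMessage(e)),
          file = log, append = TRUE))
  }
  cat(sprintf("done: %d ok, %d failed\n",
              length(results), length(failures)),
      file = log, append = TRUE)
  invisible(list(nOk = length(results), nFailed = length(failures),
                 failures = failures,
                 status = as.integer(length(failures) > 0),
                 table = table))
}
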