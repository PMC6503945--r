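# End-to-end orchestration: simulate -> detect -> select -> epoch -> cluster
# test -> controls, with a reproducibility manifest.

.pipelineDefaults <- function() list(
  nSubjects = 8L,
  seed = 1L,
  simulation = list(sfreq = 250, nChannels = 24, nTrialsPerCondition = 18),
  detection = list(rThreshold = 0.7, tThreshold = 0.6,
                   extrasystoleFraction = 0.30),
  selection = list(startOffset = 2, endOffset = 0.4, minNextR = 0.4),
  epochs = list(lowpass = 30, window = c(-0.1, 0.4), artifactMultiple = 3),
  cluster = list(nPermutations = 1000L, thresholdP = 0.05,
                 minNeighbors = 4, alpha = 0.05, adjacencyK = 6),
  analysisWindow = c(80, 350),
  useGroundTruthPeaks = FALSE,
  runStratification = TRUE,
  runGlm = TRUE,
  outDir = NULL)

#' Assemble and validate a pipeline configuration
#'
#' One nested configuration drives the whole pipeline; every stage
#' parameter (correlation thresholds, the 0.4 s next-R rule, the 2 s
#' post-onset offset, the 80-350 ms analysis window, the 30 Hz low-pass,
#' permutation counts, the 2% stratification tolerance, the +/-1 condition
#' coding, the component caps) is a configurable default, never a
#' hard-coded constant. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults (top-level scalars, or named lists
#'   for the `simulation`, `detection`, `selection`, `epochs`, `cluster`
#'   sections). `simulation` entries are passed to [simulationConfig()].
#' @return validated configuration list.
#' @export
pipelineConfig <- function(...) {
  cfg <- .pipelineDefaults()
  over <- list(...)
  if (length(over) && is.null(names(over)))
    stop("pipeline configuration overrides must be named")
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown configuration key(s): ",
                        paste(bad, collapse = ", "))
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      if (nm == "simulation") {
        badSim <- setdiff(names(over[[nm]]),
                          names(formals(simulationConfig)))
        if (length(badSim)) stop("unknown simulation key(s): ",
                                 paste(badSim, collapse = ", "))
      } else {
        badSub <- setdiff(names(over[[nm]]), names(cfg[[nm]]))
        if (length(badSub)) stop("unknown ", nm, " key(s): ",
                                 paste(badSub, collapse = ", "))
      }
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else cfg[[nm]] <- over[[nm]]
  }
  cfg
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with (a subset of) the [pipelineConfig()] keys.
#' @return validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipelineConfig, raw)
}

#' Promote a ground-truth oracle to a CardiacEvents object
#'
#' Wraps the generator's true peak times as fully valid
#' [CardiacEvents-class], bypassing detection — useful for oracle-driven
#' testing and noise-free constructions.
#'
#' @param gt a [GroundTruth-class] object.
#' @return a [CardiacEvents-class] object with every beat valid.
#' @export
groundTruthEvents <- function(gt) {
  n <- length(gt@rTimes)
  new("CardiacEvents", rTimes = gt@rTimes, tTimes = gt@tTimes,
      valid = rep(TRUE, n), exclusionReason = rep("none", n))
}
.groundTruthEvents <- groundTruthEvents

#' Run the full HER pipeline on simulated subjects
#'
#' Simulates `nSubjects` sessions (one derived seed each), detects cardiac
#' events on the ECG (or takes the ground-truth peaks when configured),
#' applies the heartbeat eligibility rules, extracts and averages
#' T-peak-locked epochs per condition, runs the spatio-temporal cluster
#' permutation test on the group, and optionally re-tests the leading
#' cluster's amplitude after arousal stratification and fits the trial-level
#' GLMs. Every exclusion is counted in the returned manifest.
#'
#' @param config list from [pipelineConfig()].
#' @return list with `result` ([ClusterTestResult-class]), `herAverages`
#'   (per-subject condition averages), `amplitudes` (per-subject, per-trial
#'   cluster amplitudes for the leading cluster, when one exists),
#'   `stratification`, `glm`, and `manifest` (config hash, seeds, per-stage
#'   record counts).
#' @export
runPipeline <- function(config = pipelineConfig()) {
  nSub <- config$nSubjects
  seeds <- childSeeds(config$seed, nSub)
  simArgs <- config$simulation
  subjects <- vector("list", nSub)
  counts <- data.frame(subject = seq_len(nSub), beatsDetected = 0L,
                       beatsValid = 0L, beatsEligible = 0L,
                       epochsKept = 0L, trialsRated = 0L)
  arrays <- NULL
  adjacency <- NULL
  winIdx <- NULL

  for (s in seq_len(nSub)) {
    ses <- simulateSession(do.call(simulationConfig,
                                   c(list(seed = seeds[s]), simArgs)))
    events <- if (config$useGroundTruthPeaks) {
      .groundTruthEvents(ses$groundTruth)
    } else {
      det <- config$detection
      detectCardiacEvents(ses$recording, rThreshold = det$rThreshold,
                          tThreshold = det$tThreshold,
                          extrasystoleFraction = det$extrasystoleFraction)
    }
    selArgs <- config$selection
    eligible <- selectHeartbeats(ses$trials, events,
                                 startOffset = selArgs$startOffset,
                                 endOffset = selArgs$endOffset,
                                 minNextR = selArgs$minNextR)
    ep <- extractHEREpochs(ses$recording, eligible,
                           lowpass = config$epochs$lowpass,
                           window = config$epochs$window,
                           artifactMultiple = config$epochs$artifactMultiple)
    avg <- averageHER(ep)
    if (is.null(adjacency)) {
      adjacency <- sensorAdjacency(channelPositions(ses$recording),
                                   k = config$cluster$adjacencyK)
      tms <- epochTimes(ep)
      winIdx <- which(tms >= config$analysisWindow[1] &
                      tms <= config$analysisWindow[2])
      arrays <- list(
        self = array(NA_real_, c(nSub, length(channelLabels(ses$recording)),
                                 length(winIdx))),
        other = array(NA_real_, dim = c(nSub,
                                        length(channelLabels(ses$recording)),
                                        length(winIdx))))
    }
    arrays$self[s, , ] <- avg@averages[["Self"]][, winIdx]
    arrays$other[s, , ] <- avg@averages[["Other"]][, winIdx]
    counts$beatsDetected[s] <- length(rTimes(events))
    counts$beatsValid[s] <- sum(validBeats(events))
    counts$beatsEligible[s] <- nrow(eligible)
    counts$epochsKept[s] <- nrow(epochInfo(ep))
    counts$trialsRated[s] <- sum(!is.na(ses$trials$arousal))
    subjects[[s]] <- list(trials = ses$trials, eligible = eligible,
                          epochs = ep, averages = avg)
  }

  cl <- config$cluster
  result <- clusterPermutationTest(arrays$self, arrays$other, adjacency,
                                   nPermutations = cl$nPermutations,
                                   seed = config$seed + 1,
                                   thresholdP = cl$thresholdP,
                                   minNeighbors = cl$minNeighbors,
                                   alpha = cl$alpha)

  lead <- if (length(clusters(result))) clusters(result)[[1]] else NULL
  amplitudes <- stratification <- glmOut <- NULL
  if (!is.null(lead)) {
    tms <- epochTimes(subjects[[1]]$epochs)[winIdx]
    wMs <- range(tms[unique(lead$members[, "time"])])
    amplitudes <- lapply(seq_len(nSub), function(s) {
      amp <- clusterAmplitude(subjects[[s]]$epochs, lead$channels, wMs,
                              groupBy = "trial")
      merge(amp, subjects[[s]]$trials[, c("trial", "perspective", "valence",
                                          "arousal")], by = "trial")
    })
    condDiff <- function(amp, keepTrials = NULL) {
      if (!is.null(keepTrials)) amp <- amp[amp$trial %in% keepTrials, ]
      mean(amp$amplitude[amp$condition == "Self"]) -
        mean(amp$amplitude[amp$condition == "Other"])
    }
    if (isTRUE(config$runStratification)) {
      diffs <- vapply(seq_len(nSub), function(s) {
        tr <- subjects[[s]]$trials
        aIdx <- which(tr$condition == "Self")
        bIdx <- which(tr$condition == "Other")
        st <- stratify(tr$arousal[aIdx], tr$arousal[bIdx],
                       seed = seeds[s] + 13)
        keep <- c(tr$trial[aIdx[st@retainedA]], tr$trial[bIdx[st@retainedB]])
        c(pre = condDiff(amplitudes[[s]]),
          post = condDiff(amplitudes[[s]], keep))
      }, numeric(2))
      stratification <- list(preMeanDiff = mean(diffs["pre", ]),
                             postMeanDiff = mean(diffs["post", ]),
                             perSubject = t(diffs))
    }
    if (isTRUE(config$runGlm)) {
      fits <- lapply(amplitudes, fitHERGlm)
      glmOut <- list(betas = do.call(rbind, lapply(fits, function(f) f@beta)),
                     group = groupBetaTest(fits))
    }
  }

  manifest <- list(
    configHash = configHash(config[setdiff(names(config), "outDir")]),
    seed = config$seed, subjectSeeds = seeds,
    packageVersion = as.character(utils::packageVersion("herpipe")),
    counts = counts,
    nSignificantClusters = sum(vapply(clusters(result),
                                      function(x) isTRUE(x$significant),
                                      logical(1))))
  out <- list(result = result, herAverages = lapply(subjects, `[[`, "averages"),
              amplitudes = amplitudes, stratification = stratification,
              glm = glmOut, manifest = manifest)
  if (!is.null(config$outDir)) writePipelineReport(out, config$outDir)
  out
}

#' Write a markdown + JSON pipeline report
#'
#' @param run output of [runPipeline()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writePipelineReport <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cls <- lapply(clusters(run$result), function(x)
    list(sumT = x$sumT, sign = x$sign, p = x$p,
         significant = x$significant, cohenD = x$cohenD,
         channels = x$channels, nSamples = nrow(x$members)))
  jsonlite::write_json(list(clusters = cls, manifest = run$manifest),
                       file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  if (!is.null(run$glm))
    utils::write.csv(run$glm$group, file.path(dir, "glm_group.csv"),
                     row.names = FALSE)
  md <- c("# HER pipeline report", "",
          sprintf("- subjects: %d", nrow(run$manifest$counts)),
          sprintf("- mean eligible beats/subject: %.1f",
                  mean(run$manifest$counts$beatsEligible)),
          sprintf("- clusters found: %d (significant: %d)",
                  length(clusters(run$result)),
                  run$manifest$nSignificantClusters))
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

#' Plot condition-average HERs for a sensor set
#'
#' Base-graphics time-course plot of the condition-mean HER averaged over
#' the given sensors.
#'
#' @param average an [HERAverage-class] object.
#' @param sensors channel labels to average (default: all).
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the plotted matrix (time x condition).
#' @export
plotHER <- function(average, sensors = NULL, ...) {
  labs <- average@channelLabels
  if (is.null(sensors)) sensors <- labs
  idx <- match(sensors, labs)
  stopifnot(!anyNA(idx))
  M <- vapply(average@averages, function(m) colMeans(m[idx, , drop = FALSE]),
              numeric(length(average@times)))
  graphics::matplot(average@times, M, type = "l", lty = 1,
                    xlab = "time after T-peak (ms)", ylab = "amplitude", ...)
  graphics::legend("topright", legend = colnames(M), lty = 1,
                   col = seq_len(ncol(M)), bty = "n")
  invisible(M)
}
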