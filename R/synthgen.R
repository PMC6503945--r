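#' Create a simulation configuration
#'
#' Returns a [SimulationConfig-class] with the study-condition defaults: a
#' cardiac renewal process with mean interbeat interval 854 ms (SD 50 ms), a
#' 280 ms R-to-T lag, 36 trials per condition whose imagination periods last
#' 6.7-7.3 s (fixation 1-1.3 s, instruction 2.3 s, inter-trial interval
#' 4.5-5.4 s), and arousal ratings centered on 3.4 (Self) vs 3.0 (Other) on
#' the 1-5 scale. The planted heartbeat-evoked effect sits over posterior
#' sensors in the 307-326 ms post-T-peak window by default.
#'
#' @param seed RNG seed for the session.
#' @param sfreq sampling rate, Hz. 1000 mirrors the acquisition rate; 250 is
#'   adequate for fast sensor-level simulations (all rules are specified in
#'   seconds/ms, never samples).
#' @param nChannels number of sensor channels (default 102 magnetometer-like
#'   sensors).
#' @param nTrialsPerCondition trials per condition.
#' @param ibiMean,ibiSd interbeat-interval mean / SD, ms.
#' @param imaginationRange,fixationRange,itiRange timing ranges, s.
#' @param instructionDuration,responseDuration fixed stage durations, s.
#' @param rToTLag R-peak to T-apex lag, ms.
#' @param effectSensors channel labels carrying the planted effect;
#'   `character(0)` picks a posterior patch of 8 automatically.
#' @param effectWindow planted latency window after the T-peak, ms; must lie
#'   inside the [80, 350] ms analysis span.
#' @param effectAmplitudeSelf,effectAmplitudeOther planted amplitudes
#'   (sensor units). Negative-going Self < Other by default, giving a
#'   negative Self-minus-Other cluster.
#' @param cardiacArtifactGain gain of the cardiac-field artifact (mixed into
#'   channels with a smooth signed left-right topography).
#' @param sensorNoiseSd,ecgNoiseSd noise levels.
#' @param arousalMeanSelf,arousalMeanOther,ratingSd rating distribution
#'   parameters (discretized truncated Gaussians).
#' @param driftAmplitude slow non-heartbeat-locked Self drift (0 = off).
#' @return a validated [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(seed = 1, sfreq = 250, nChannels = 20)
#' @export
simulationConfig <- function(seed = 1L, sfreq = 1000, nChannels = 102L,
                             nTrialsPerCondition = 36L,
                             ibiMean = 854, ibiSd = 50,
                             imaginationRange = c(6.7, 7.3),
                             fixationRange = c(1.0, 1.3),
                             instructionDuration = 2.3,
                             responseDuration = 4.5,
                             itiRange = c(4.5, 5.4),
                             rToTLag = 280,
                             effectSensors = character(0),
                             effectWindow = c(307, 326),
                             effectAmplitudeSelf = -1.5,
                             effectAmplitudeOther = -0.5,
                             cardiacArtifactGain = 0.5,
                             sensorNoiseSd = 1,
                             ecgNoiseSd = 0.03,
                             arousalMeanSelf = 3.4, arousalMeanOther = 3.0,
                             ratingSd = 1.0,
                             driftAmplitude = 0) {
  new("SimulationConfig",
      seed = as.integer(seed), sfreq = sfreq,
      nChannels = as.integer(nChannels),
      nTrialsPerCondition = as.integer(nTrialsPerCondition),
      ibiMean = ibiMean, ibiSd = ibiSd,
      imaginationRange = imaginationRange, fixationRange = fixationRange,
      instructionDuration = instructionDuration,
      responseDuration = responseDuration, itiRange = itiRange,
      rToTLag = rToTLag,
      effectSensors = effectSensors, effectWindow = effectWindow,
      effectAmplitudeSelf = effectAmplitudeSelf,
      effectAmplitudeOther = effectAmplitudeOther,
      cardiacArtifactGain = cardiacArtifactGain,
      sensorNoiseSd = sensorNoiseSd, ecgNoiseSd = ecgNoiseSd,
      arousalMeanSelf = arousalMeanSelf, arousalMeanOther = arousalMeanOther,
      ratingSd = ratingSd, driftAmplitude = driftAmplitude)
}

# ECG morphology: sum of Gaussian bumps per beat. Amplitudes in units of the
# R deflection; centers in ms relative to the R-peak.
.ecgBumps <- function(rToTLag) {
  data.frame(
    wave   = c("P", "Q", "R", "S", "T"),
    amp    = c(0.12, -0.12, 1.00, -0.18, 0.35),
    center = c(-160, -22, 0, 25, rToTLag),
    sd     = c(22, 8, 11, 9, 55))
}

# Add Gaussian bumps centered at `centers` (s) to `trace` in place.
.addBumps <- function(trace, sfreq, centers, amp, sdMs, shapeFun = NULL) {
  n <- length(trace)
  half <- ceiling(4 * sdMs / 1000 * sfreq)
  rel <- seq(-half, half)
  shape <- amp * exp(-0.5 * (rel / sfreq * 1000 / sdMs)^2)
  for (tc in centers) {
    i0 <- round(tc * sfreq) + 1L
    idx <- i0 + rel
    keep <- idx >= 1L & idx <= n
    trace[idx[keep]] <- trace[idx[keep]] + shape[keep]
  }
  trace
}

# Renewal R-peak times over [0, duration], truncated-positive normal IBIs.
.renewalRTimes <- function(ibiMean, ibiSd, duration) {
  ibiS <- ibiMean / 1000
  lower <- max(0.02, 0.35 * ibiS)  # keeps morphology non-overlapping
  nGuess <- ceiling(duration / ibiS * 1.4) + 10
  drawIbis <- function(n) {
    if (ibiSd == 0) return(rep(ibiS, n))
    x <- stats::rnorm(n, ibiS, ibiSd / 1000)
    while (any(bad <- x <= lower))
      x[bad] <- stats::rnorm(sum(bad), ibiS, ibiSd / 1000)
    x
  }
  first <- if (ibiSd == 0) ibiS / 2 else stats::runif(1, 0.1, ibiS)
  r <- cumsum(c(first, drawIbis(nGuess)))
  while (r[length(r)] < duration) r <- c(r, r[length(r)] + drawIbis(50))
  r[r <= duration - 0.55]  # leave room for the full T wave
}

.simulateECGCore <- function(config, duration, nLeads = 2) {
  sf <- config@sfreq
  n <- round(duration * sf)
  rT <- .renewalRTimes(config@ibiMean, config@ibiSd, duration)
  if (!length(rT)) stop("duration too short for a single heartbeat")
  tT <- rT + config@rToTLag / 1000
  bumps <- .ecgBumps(config@rToTLag)
  clean <- numeric(n)
  for (k in seq_len(nrow(bumps)))
    clean <- .addBumps(clean, sf, rT + bumps$center[k] / 1000,
                       bumps$amp[k], bumps$sd[k])
  leadNames <- c("II", "III", "I", "aVF", "aVL", "aVR", "V1")[seq_len(nLeads)]
  leadGain <- c(1, 0.75, 0.55, 0.85, -0.4, -0.9, 0.6)[seq_len(nLeads)]
  ecg <- stats::setNames(vector("list", nLeads), leadNames)
  for (l in seq_len(nLeads)) {
    x <- leadGain[l] * clean
    if (config@ecgNoiseSd > 0)
      x <- x + butterFilter(stats::rnorm(n, sd = config@ecgNoiseSd), sf,
                            low = NULL, high = 40)
    ecg[[l]] <- x
  }
  list(ecg = ecg, cleanWave = clean, rTimes = rT, tTimes = tT)
}

#' Simulate a multi-lead ECG with known peak times
#'
#' Generates an ECG as a renewal process of heartbeats (truncated-positive
#' normal interbeat intervals) where every beat contributes P/Q/R/S/T
#' Gaussian bumps, the T apex lagging the R-peak by `rToTLag`, plus
#' band-limited additive noise. The true peak times are returned as a
#' [GroundTruth-class] oracle.
#'
#' @param config a [SimulationConfig-class].
#' @param duration trace duration, s (>= 5).
#' @param nLeads number of ECG leads to synthesize (lead II first).
#' @param seed RNG seed (defaults to the config seed).
#' @return list with `ecg` (named list of per-lead traces), `groundTruth`
#'   (a [GroundTruth-class] with the true R/T times), and `sfreq`.
#' @examples
#' sim <- simulateECG(simulationConfig(seed = 2), duration = 30)
#' length(rTimes(sim$groundTruth))
#' @export
simulateECG <- function(config, duration, nLeads = 2, seed = config@seed) {
  validObject(config)
  if (duration < 5) stop("duration must be >= 5 s")
  core <- withSeed(seed, .simulateECGCore(config, duration, nLeads))
  gt <- new("GroundTruth", rTimes = core$rTimes, tTimes = core$tTimes,
            effectSensors = character(0), effectWindow = config@effectWindow,
            blinkIntervals = matrix(numeric(0), ncol = 2))
  list(ecg = core$ecg, groundTruth = gt, sfreq = config@sfreq)
}

# Discretized truncated Gaussian ratings on an integer scale.
.simulateRatings <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, round(stats::rnorm(n, mean, sd))))
}

.simulateTrialFrame <- function(config) {
  nPerCond <- config@nTrialsPerCondition
  nTot <- 2L * nPerCond
  condition <- sample(rep(c("Self", "Other"), nPerCond))
  nBlocks <- max(1L, min(4L, nTot %/% 2L))
  block <- ceiling(seq_len(nTot) / ceiling(nTot / nBlocks))
  t <- 2.0
  fix <- stats::runif(nTot, config@fixationRange[1], config@fixationRange[2])
  imag <- stats::runif(nTot, config@imaginationRange[1], config@imaginationRange[2])
  iti <- stats::runif(nTot, config@itiRange[1], config@itiRange[2])
  fixation_onset <- instruction_onset <- imagination_onset <-
    imagination_offset <- numeric(nTot)
  for (i in seq_len(nTot)) {
    fixation_onset[i] <- t
    instruction_onset[i] <- t + fix[i]
    imagination_onset[i] <- instruction_onset[i] + config@instructionDuration
    imagination_offset[i] <- imagination_onset[i] + imag[i]
    t <- imagination_offset[i] + config@responseDuration + iti[i]
  }
  self <- condition == "Self"
  perspective <- integer(nTot)
  perspective[self] <- .simulateRatings(sum(self), 3.6, config@ratingSd, 1, 5)
  perspective[!self] <- .simulateRatings(sum(!self), 3.5, config@ratingSd, 1, 5)
  valence <- .simulateRatings(nTot, 0.5, 1.1, -2, 2)
  arousal <- integer(nTot)
  arousal[self] <- .simulateRatings(sum(self), config@arousalMeanSelf,
                                    config@ratingSd, 1, 5)
  arousal[!self] <- .simulateRatings(sum(!self), config@arousalMeanOther,
                                     config@ratingSd, 1, 5)
  data.frame(trial = seq_len(nTot), block = block, condition = condition,
             fixation_onset = fixation_onset,
             instruction_onset = instruction_onset,
             imagination_onset = imagination_onset,
             imagination_offset = imagination_offset,
             perspective = perspective, valence = valence, arousal = arousal,
             responded = TRUE)
}

#' Validate a trial table
#'
#' Checks the documented trial-table contract: one row per trial, equal
#' trial counts per condition, imagination durations inside the configured
#' range, and ratings within their scale bounds.
#'
#' @param trials trial table data.frame.
#' @param imaginationRange allowed imagination duration range, s.
#' @return invisibly `TRUE`; errors otherwise.
#' @export
validateTrialTable <- function(trials, imaginationRange = c(6.7, 7.3)) {
  need <- c("trial", "condition", "imagination_onset", "imagination_offset",
            "perspective", "valence", "arousal", "responded")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("trial table misses columns: ",
                         paste(miss, collapse = ", "))
  dur <- trials$imagination_offset - trials$imagination_onset
  if (any(dur < imaginationRange[1] - 1e-9 | dur > imaginationRange[2] + 1e-9))
    stop("imagination durations outside the configured range")
  tab <- table(trials$condition)
  if (length(tab) != 2 || tab[1] != tab[2])
    stop("trial counts per condition must be equal")
  ok <- function(x, lo, hi) all(is.na(x) | (x >= lo & x <= hi))
  if (!ok(trials$perspective, 1, 5) || !ok(trials$arousal, 1, 5) ||
      !ok(trials$valence, -2, 2))
    stop("ratings outside scale bounds")
  invisible(TRUE)
}

# Half-sine bump of unit peak amplitude over [w1, w2] ms after each T-peak.
.addEffectBumps <- function(data, sfreq, rows, tTimes, window, amplitude) {
  if (!length(rows) || !length(tTimes) || amplitude == 0) return(data)
  w <- window / 1000
  nSamp <- ncol(data)
  rel <- seq(round(w[1] * sfreq), round(w[2] * sfreq))
  span <- max(length(rel) - 1L, 1L)
  shape <- amplitude * sin(pi * (seq_along(rel) - 1) / span)
  for (tt in tTimes) {
    idx <- round(tt * sfreq) + 1L + rel
    keep <- idx >= 1L & idx <= nSamp
    if (!any(keep)) next
    data[rows, idx[keep]] <- data[rows, idx[keep]] +
      rep(shape[keep], each = length(rows))
  }
  data
}

#' Simulate a complete synthetic session
#'
#' Generates one subject's session: continuous sensor data (sensor noise +
#' cardiac-field artifact + a condition-dependent heartbeat-evoked bump
#' planted after every T-peak inside each trial's imagination period), a
#' multi-lead ECG, auxiliary traces (vertical EOG, EMG, pupil with blinks),
#' a trial table with Perspective/Valence/Arousal ratings, and the ground
#' truth of everything planted.
#'
#' The cardiac renewal process runs continuously across the session;
#' heartbeats are not phase-locked to trial onsets. With
#' `sensors = FALSE` the (expensive) sensor matrix is skipped and only the
#' ECG, trial table and ground truth are produced — sufficient for
#' heartbeat-bookkeeping studies.
#'
#' @param config a [SimulationConfig-class].
#' @param sensors generate the sensor-channel matrix? (default TRUE)
#' @param nLeads number of ECG leads.
#' @return list with elements `recording` ([Recording-class]), `trials`
#'   (data.frame), `groundTruth` ([GroundTruth-class]) and `config` (the
#'   config actually used, with `effectSensors` filled in).
#' @examples
#' ses <- simulateSession(simulationConfig(seed = 3, sfreq = 250,
#'                                         nChannels = 12,
#'                                         nTrialsPerCondition = 2))
#' ses$recording
#' @export
simulateSession <- function(config, sensors = TRUE, nLeads = 2) {
  validObject(config)
  withSeed(config@seed, {
    trials <- .simulateTrialFrame(config)
    duration <- max(trials$imagination_offset) + config@responseDuration + 3
    sf <- config@sfreq
    nSamp <- round(duration * sf)
    core <- .simulateECGCore(config, duration, nLeads)

    nCh <- config@nChannels
    pos <- sensorLayout(nCh)
    labels <- rownames(pos)
    effectSensors <- config@effectSensors
    if (!length(effectSensors)) {
      # posterior patch: most-posterior sensor and its nearest neighbors
      postIdx <- which.min(pos[, "y"])
      d <- sqrt((pos[, "layout2d_x"] - pos[postIdx, "layout2d_x"])^2 +
                (pos[, "layout2d_y"] - pos[postIdx, "layout2d_y"])^2)
      effectSensors <- labels[order(d)[seq_len(min(8, nCh))]]
    } else if (!all(effectSensors %in% labels)) {
      stop("effectSensors must be a subset of the channel labels")
    }

    if (sensors) {
      data <- matrix(stats::rnorm(nCh * nSamp, sd = config@sensorNoiseSd),
                     nrow = nCh)
      if (config@cardiacArtifactGain != 0) {
        gains <- config@cardiacArtifactGain * pos[, "x"]
        data <- data + outer(gains, core$cleanWave)
      }
      rowsEff <- match(effectSensors, labels)
      for (i in seq_len(nrow(trials))) {
        tt <- core$tTimes[core$tTimes >= trials$imagination_onset[i] &
                          core$tTimes <= trials$imagination_offset[i]]
        amp <- if (trials$condition[i] == "Self")
          config@effectAmplitudeSelf else config@effectAmplitudeOther
        data <- .addEffectBumps(data, sf, rowsEff, tt,
                                config@effectWindow, amp)
        if (config@driftAmplitude != 0 && trials$condition[i] == "Self") {
          # slow condition-dependent offset: raised-cosine ramps outside a
          # plateau that covers the whole imagination period, so the drift
          # is constant wherever heartbeat-locked epochs can sample it
          i0 <- max(1L, round((trials$imagination_onset[i] - 0.5) * sf) + 1L)
          i1 <- min(nSamp, round((trials$imagination_offset[i] + 0.5) * sf))
          p0 <- round(trials$imagination_onset[i] * sf) + 1L
          p1 <- round(trials$imagination_offset[i] * sf)
          idx <- i0:i1
          w <- rep(1, length(idx))
          up <- idx < p0
          w[up] <- 0.5 - 0.5 * cos(pi * (idx[up] - i0) / (p0 - i0))
          dn <- idx > p1
          w[dn] <- 0.5 + 0.5 * cos(pi * (idx[dn] - p1) / (i1 - p1))
          data[rowsEff, idx] <- data[rowsEff, idx] +
            rep(config@driftAmplitude * w, each = length(rowsEff))
        }
      }
    } else {
      data <- matrix(numeric(0), nrow = 0, ncol = nSamp)
      pos <- matrix(numeric(0), nrow = 0, ncol = 5,
                    dimnames = list(NULL, colnames(sensorLayout(2))))
      labels <- character(0)
    }

    # auxiliary traces: EOG/EMG noise, pupil with blinks
    nBlinks <- stats::rpois(1, duration * 0.12)
    blinkStart <- sort(stats::runif(nBlinks, 1, duration - 1))
    blinkDur <- stats::runif(nBlinks, 0.1, 0.25)
    blinks <- mergeIntervals(cbind(blinkStart, blinkStart + blinkDur))
    tAxis <- seq_len(nSamp) / sf
    veog <- stats::rnorm(nSamp, sd = 0.3)
    pupil <- 0.3 * sin(2 * pi * 0.08 * tAxis) + stats::rnorm(nSamp, sd = 0.03)
    if (nrow(blinks)) {
      for (k in seq_len(nrow(blinks))) {
        i0 <- max(1L, round(blinks[k, 1] * sf))
        i1 <- min(nSamp, round(blinks[k, 2] * sf))
        veog[i0:i1] <- veog[i0:i1] + 5
        pupil[i0:i1] <- pupil[i0:i1] - 4     # occlusion artifact
      }
    }
    aux <- c(core$ecg,
             list(VEOG = veog, EMG = stats::rnorm(nSamp, sd = 0.5),
                  pupil = pupil))
    names(aux)[seq_along(core$ecg)] <- paste0("ECG_", names(core$ecg))

    dimnames(data) <- NULL
    recording <- new("Recording", data = data, sfreq = sf,
                     channelLabels = labels, channelPositions = pos,
                     aux = aux)
    gt <- new("GroundTruth", rTimes = core$rTimes, tTimes = core$tTimes,
              effectSensors = effectSensors,
              effectWindow = config@effectWindow,
              blinkIntervals = blinks)
    usedConfig <- config
    usedConfig@effectSensors <- effectSensors
    list(recording = recording, trials = trials, groundTruth = gt,
         config = usedConfig)
  })
}
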