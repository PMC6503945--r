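# Heartbeat eligibility rules, T-peak-locked epoch extraction/averaging and
# cluster amplitudes.

#' Select eligible heartbeats per trial
#'
#' Applies the heartbeat eligibility rules: keep valid T-peaks falling
#' within `[imagination onset + 2 s, imagination offset - 0.4 s]`; drop
#' T-peaks followed by the next R-peak in less than 0.4 s (this guarantees
#' the [80, 350] ms analysis window never overlaps the following R-peak
#' artifact); drop beats flagged invalid; drop trials lacking any of the
#' three ratings or without a recorded behavioral response.
#'
#' @param trials trial table (see [validateTrialTable()]).
#' @param events a [CardiacEvents-class] object.
#' @param startOffset window start after imagination onset, s (default 2).
#' @param endOffset window end before imagination offset, s (default 0.4).
#' @param minNextR minimal tolerated T-to-next-R gap, s (default 0.4).
#' @return data.frame with one row per eligible heartbeat: `trial`,
#'   `condition`, `tTime` (s, absolute).
#' @examples
#' ses <- simulateSession(simulationConfig(seed = 6, sfreq = 250,
#'                                         nChannels = 4,
#'                                         nTrialsPerCondition = 3),
#'                        sensors = FALSE)
#' ev <- new("CardiacEvents", rTimes = rTimes(ses$groundTruth),
#'           tTimes = tTimes(ses$groundTruth),
#'           valid = rep(TRUE, length(rTimes(ses$groundTruth))),
#'           exclusionReason = rep("none", length(rTimes(ses$groundTruth))))
#' nrow(selectHeartbeats(ses$trials, ev))
#' @export
selectHeartbeats <- function(trials, events, startOffset = 2,
                             endOffset = 0.4, minNextR = 0.4) {
  rT <- events@rTimes
  tT <- events@tTimes
  ok <- events@valid & !is.na(tT)
  tOk <- tT[ok]
  # gap to the next R-peak (any detected R, valid or not)
  nxt <- findInterval(tOk, rT) + 1L
  gap <- ifelse(nxt <= length(rT), rT[pmin(nxt, length(rT))] - tOk, Inf)
  tOk <- tOk[gap >= minNextR]

  rated <- !is.na(trials$perspective) & !is.na(trials$valence) &
    !is.na(trials$arousal) & as.logical(trials$responded)
  out <- vector("list", nrow(trials))
  for (i in which(rated)) {
    lo <- trials$imagination_onset[i] + startOffset
    hi <- trials$imagination_offset[i] - endOffset
    sel <- tOk[tOk >= lo & tOk <= hi]
    if (length(sel))
      out[[i]] <- data.frame(trial = trials$trial[i],
                             condition = trials$condition[i], tTime = sel)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(trial = integer(0), condition = character(0),
                      tTime = numeric(0))
  rownames(res) <- NULL
  res
}

#' Extract T-peak-locked HER epochs
#'
#' Low-pass filters the (cleaned) sensor data at 30 Hz (4th-order zero-phase
#' Butterworth), cuts epochs from 0.1 s before to 0.4 s after each eligible
#' T-peak, and drops epochs that (i) run off the recording edge or (ii)
#' violate an automatic amplitude rule standing in for visual artifact
#' screening: peak-to-peak amplitude on any channel above
#' `artifactMultiple` times that channel's median epoch peak-to-peak (an
#' adaptive criterion that tracks the band-limited background level). No
#' baseline correction is applied by default.
#'
#' @param recording a cleaned [Recording-class].
#' @param eligible data.frame from [selectHeartbeats()].
#' @param lowpass low-pass corner, Hz (default 30; NULL to skip).
#' @param window epoch limits relative to the T-peak, s.
#' @param artifactMultiple multiple of the channel-wise median epoch
#'   peak-to-peak above which an epoch is rejected (default 3; `Inf`
#'   disables).
#' @param baseline optional baseline window, s relative to the T-peak, whose
#'   mean is subtracted per channel (default `NULL`: off).
#' @return an [HEREpochs-class] object; rejected candidates are recorded in
#'   its drop log.
#' @export
extractHEREpochs <- function(recording, eligible, lowpass = 30,
                             window = c(-0.1, 0.4), artifactMultiple = 3,
                             baseline = NULL) {
  sf <- sfreq(recording)
  dat <- sensorData(recording)
  if (!nrow(dat)) stop("recording carries no sensor channels")
  if (!is.null(lowpass)) dat <- butterFilter(dat, sf, low = NULL, high = lowpass)
  rel <- seq(round(window[1] * sf), round(window[2] * sf))
  times <- rel / sf * 1000
  nCh <- nrow(dat); nT <- length(rel); nS <- ncol(dat)

  keep <- logical(nrow(eligible))
  reason <- character(nrow(eligible))
  i0 <- round(eligible$tTime * sf) + 1L
  edgeOk <- (i0 + rel[1]) >= 1L & (i0 + rel[nT]) <= nS
  reason[!edgeOk] <- "recording_edge"

  idxList <- which(edgeOk)
  tensor <- array(NA_real_, c(length(idxList), nCh, nT))
  for (k in seq_along(idxList))
    tensor[k, , ] <- dat[, i0[idxList[k]] + rel, drop = FALSE]
  if (is.finite(artifactMultiple) && length(idxList) > 1) {
    ptp <- .ptpMatrix(tensor)
    medPtp <- apply(ptp, 2, stats::median)
    bad <- ptp > matrix(artifactMultiple * medPtp, nrow(ptp), nCh,
                        byrow = TRUE)
    artBad <- rowSums(bad) > 0
    reason[idxList[artBad]] <- "amplitude_artifact"
    tensor <- tensor[!artBad, , , drop = FALSE]
    idxList <- idxList[!artBad]
  }
  keep[idxList] <- TRUE
  if (!is.null(baseline) && length(idxList)) {
    bIdx <- which(times >= baseline[1] * 1000 & times <= baseline[2] * 1000)
    for (k in seq_along(idxList))
      tensor[k, , ] <- tensor[k, , ] - rowMeans(tensor[k, , bIdx, drop = FALSE])
  }
  info <- data.frame(trial = eligible$trial[keep],
                     condition = eligible$condition[keep],
                     tTime = eligible$tTime[keep])
  drop <- data.frame(trial = eligible$trial[!keep],
                     tTime = eligible$tTime[!keep],
                     reason = reason[!keep])
  new("HEREpochs", data = tensor, times = times,
      channelLabels = channelLabels(recording), epochInfo = info,
      sfreq = sf, dropLog = drop)
}

#' Average HER epochs per condition
#'
#' Pointwise mean across heartbeats (heartbeat-weighted, not
#' trial-weighted) per condition.
#'
#' @param epochs an [HEREpochs-class] object.
#' @param conditions conditions to average (default: all present).
#' @return an [HERAverage-class] object.
#' @export
averageHER <- function(epochs, conditions = NULL) {
  info <- epochInfo(epochs)
  if (is.null(conditions)) conditions <- sort(unique(info$condition))
  avgs <- stats::setNames(vector("list", length(conditions)), conditions)
  nE <- stats::setNames(integer(length(conditions)), conditions)
  for (cond in conditions) {
    sel <- which(info$condition == cond)
    if (!length(sel)) stop("no epochs for condition '", cond, "'")
    sub <- epochData(epochs)[sel, , , drop = FALSE]
    avgs[[cond]] <- apply(sub, c(2, 3), mean)
    nE[cond] <- length(sel)
  }
  new("HERAverage", averages = avgs, nEpochs = nE,
      times = epochTimes(epochs), channelLabels = channelLabels(epochs))
}

#' Cluster amplitude per heartbeat, trial or trial sub-window
#'
#' The cluster amplitude is the mean of the epoch data over a sensor set
#' and time window (ms after the T-peak). Grouping `"heartbeat"` returns
#' one amplitude per epoch; `"trial"` averages each trial's heartbeats;
#' `"subwindow"` restricts to heartbeats whose T-peak falls inside
#' `subwindow` (s after the imagination onset; requires `trials`) before
#' averaging per trial.
#'
#' Averaging commutes: the mean of per-heartbeat amplitudes equals the
#' amplitude of the mean waveform over the same mask.
#'
#' @param epochs an [HEREpochs-class] object.
#' @param sensors channel labels of the cluster.
#' @param window time window, ms after the T-peak (e.g. `c(307, 326)`).
#' @param groupBy `"heartbeat"`, `"trial"` or `"subwindow"`.
#' @param trials trial table (needed for `"subwindow"`).
#' @param subwindow numeric (lo, hi), s after imagination onset.
#' @return data.frame of amplitudes with grouping columns.
#' @export
clusterAmplitude <- function(epochs, sensors, window,
                             groupBy = c("heartbeat", "trial", "subwindow"),
                             trials = NULL, subwindow = NULL) {
  groupBy <- match.arg(groupBy)
  chIdx <- match(sensors, channelLabels(epochs))
  if (!length(chIdx) || anyNA(chIdx)) stop("unknown or empty sensor set")
  tIdx <- which(epochTimes(epochs) >= window[1] &
                epochTimes(epochs) <= window[2])
  if (!length(tIdx)) stop("empty time window")
  info <- epochInfo(epochs)
  sub <- epochData(epochs)[, chIdx, tIdx, drop = FALSE]
  amp <- apply(sub, 1, mean)
  if (groupBy == "heartbeat")
    return(data.frame(epoch = seq_along(amp), trial = info$trial,
                      condition = info$condition, amplitude = amp))
  if (groupBy == "subwindow") {
    if (is.null(trials) || is.null(subwindow))
      stop("subwindow grouping needs `trials` and `subwindow`")
    onset <- trials$imagination_onset[match(info$trial, trials$trial)]
    relT <- info$tTime - onset
    keep <- relT >= subwindow[1] & relT <= subwindow[2]
    amp <- amp[keep]; info <- info[keep, , drop = FALSE]
    if (!length(amp))
      return(data.frame(trial = integer(0), condition = character(0),
                        amplitude = numeric(0), nBeats = integer(0)))
  }
  agg <- tapply(amp, info$trial, mean)
  cnt <- tapply(amp, info$trial, length)
  tr <- as.integer(names(agg))
  data.frame(trial = tr,
             condition = info$condition[match(tr, info$trial)],
             amplitude = as.numeric(agg), nBeats = as.integer(cnt))
}
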