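# R/T-peak detection by sliding template correlation, beat validation and
# interbeat-interval summaries.

# Sliding Pearson correlation of `x` against `template` (length L);
# result[i] is the correlation of x[i .. i+L-1] with the template.
# FFT cross-correlation + running sums: O(n log n).
.slidingCorr <- function(x, template) {
  L <- length(template)
  n <- length(x)
  if (L >= n) stop("template length must be smaller than the trace length")
  vw <- stats::var(template) * (L - 1)
  if (!is.finite(vw) || vw <= 0)
    stop("flat (zero-variance) template: correlation undefined")
  wc <- template - mean(template)
  # linear cross-correlation via zero-padded FFT (padded to a highly
  # composite length; R's FFT degrades badly on awkward lengths)
  N <- stats::nextn(n, c(2, 3, 5))
  xp <- c(x, numeric(N - n))
  wp <- c(wc, numeric(N - L))
  cc <- Re(stats::fft(stats::fft(xp) * Conj(stats::fft(wp)),
                      inverse = TRUE)) / N
  cross <- cc[seq_len(n - L + 1)]
  cs <- cumsum(c(0, x)); cs2 <- cumsum(c(0, x * x))
  i <- seq_len(n - L + 1)
  sx <- cs[i + L] - cs[i]
  sx2 <- cs2[i + L] - cs2[i]
  vx <- pmax(sx2 - sx^2 / L, 0)
  denom <- sqrt(vx * vw)
  r <- ifelse(denom > 1e-12 * L, cross / denom, 0)
  pmin(pmax(r, -1), 1)
}

# Episodes (runs) where corr > threshold; returns start/end window indices.
.corrEpisodes <- function(r, threshold) {
  above <- r > threshold
  if (!any(above)) return(matrix(integer(0), ncol = 2))
  rl <- rle(above)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  cbind(starts[rl$values], ends[rl$values])
}

# One peak per episode: the local signal maximum within the episode,
# searched at the template's own apex offset.
.episodePeaks <- function(x, episodes, template) {
  apex <- which.max(template) - 1L
  n <- length(x)
  vapply(seq_len(nrow(episodes)), function(k) {
    lo <- min(episodes[k, 1] + apex, n)
    hi <- min(episodes[k, 2] + apex, n)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
}

#' Detect R-peaks by template correlation
#'
#' Slides a normalized (Pearson) correlation between the band-pass filtered
#' ECG and a QRS template; each maximal contiguous episode of correlation
#' above `corrThreshold` yields one R-peak, placed at the local signal
#' maximum within the episode. Normalized correlation makes the detection
#' amplitude-invariant.
#'
#' The ECG is expected band-pass filtered 0.5-40 Hz (see [butterFilter()];
#' [detectCardiacEvents()] does this for you).
#'
#' @param ecg single-lead ECG trace.
#' @param template QRS template waveform (see [qrsTemplate()]).
#' @param sfreq sampling frequency, Hz.
#' @param corrThreshold correlation threshold (default 0.7).
#' @return R-peak times, s.
#' @export
detectRPeaks <- function(ecg, template, sfreq, corrThreshold = 0.7) {
  if (!length(ecg)) stop("empty ECG trace")
  r <- .slidingCorr(ecg, template)
  ep <- .corrEpisodes(r, corrThreshold)
  if (!nrow(ep)) return(numeric(0))
  (.episodePeaks(ecg, ep, template) - 1L) / sfreq
}

#' Build a subject-specific QRS template
#'
#' Two-pass bootstrap: a generic synthetic QRS (Q/R/S Gaussian bumps) finds
#' the first `k` confident beats, whose median waveform becomes the
#' subject-specific template.
#'
#' @param ecg band-pass filtered single-lead ECG.
#' @param sfreq sampling frequency, Hz.
#' @param k number of confident beats to median-average (default 20).
#' @param halfWidth template half width, s (default 0.2). A wide template
#'   covering the P-QRS context discriminates the QRS from smooth P/T
#'   deflections, which narrow templates match spuriously under
#'   amplitude-invariant correlation.
#' @param corrThreshold bootstrap detection threshold.
#' @return numeric template vector.
#' @export
qrsTemplate <- function(ecg, sfreq, k = 20, halfWidth = 0.2,
                        corrThreshold = 0.7) {
  ecg <- ecg[seq_len(min(length(ecg), round(120 * sfreq)))]  # bootstrap pass
  rel <- seq(-halfWidth, halfWidth, by = 1 / sfreq)
  generic <- 0.12 * exp(-0.5 * ((rel + 0.160) / 0.022)^2) -
    0.12 * exp(-0.5 * ((rel + 0.022) / 0.008)^2) +
    exp(-0.5 * (rel / 0.011)^2) -
    0.18 * exp(-0.5 * ((rel - 0.025) / 0.009)^2)
  peaks <- detectRPeaks(ecg, generic, sfreq, corrThreshold)
  if (length(peaks) < 3) return(generic)
  peaks <- utils::head(peaks, k)
  idx <- round(peaks * sfreq) + 1L
  relIdx <- seq(-round(halfWidth * sfreq), round(halfWidth * sfreq))
  segs <- vapply(idx, function(i0) {
    j <- i0 + relIdx
    if (j[1] < 1 || j[length(j)] > length(ecg)) rep(NA_real_, length(relIdx))
    else ecg[j]
  }, numeric(length(relIdx)))
  tpl <- apply(segs, 1, stats::median, na.rm = TRUE)
  if (anyNA(tpl)) generic else tpl
}

#' Build a subject-specific T-wave template
#'
#' Median waveform over detected beats in a window trailing the R-peak,
#' cropped to +/- `halfWidth` around its apex.
#'
#' @param ecg band-pass filtered single-lead ECG.
#' @param sfreq sampling frequency, Hz.
#' @param rPeaks detected R-peak times, s.
#' @param searchWindow window after the R-peak searched for the T wave, s.
#' @param halfWidth template half width, s.
#' @param k number of beats to median-average.
#' @return numeric template vector.
#' @export
tTemplate <- function(ecg, sfreq, rPeaks, searchWindow = c(0.15, 0.45),
                      halfWidth = 0.08, k = 20) {
  stopifnot(length(rPeaks) >= 3)
  use <- utils::head(rPeaks, k)
  relIdx <- seq(round(searchWindow[1] * sfreq), round(searchWindow[2] * sfreq))
  segs <- vapply(round(use * sfreq) + 1L, function(i0) {
    j <- i0 + relIdx
    if (j[1] < 1 || j[length(j)] > length(ecg)) rep(NA_real_, length(relIdx))
    else ecg[j]
  }, numeric(length(relIdx)))
  med <- apply(segs, 1, stats::median, na.rm = TRUE)
  if (anyNA(med)) stop("not enough in-range beats to build a T template")
  apex <- which.max(med)
  hw <- round(halfWidth * sfreq)
  lo <- max(1, apex - hw); hi <- min(length(med), apex + hw)
  med[lo:hi]
}

#' Detect T-peaks following detected R-peaks
#'
#' Correlates the ECG with a T-wave template and, per beat, takes the local
#' signal maximum of the best correlation episode inside `(r, r + 0.4 s]`.
#' Beats without a qualifying episode are flagged `no_t_found`. The
#' correlation threshold is a per-recording tunable (T-wave morphology
#' varies between subjects); the default is 0.6.
#'
#' @param ecg band-pass filtered single-lead ECG.
#' @param rPeaks R-peak times, s.
#' @param template T-wave template (see [tTemplate()]).
#' @param sfreq sampling frequency, Hz.
#' @param corrThreshold correlation threshold (default 0.6).
#' @param maxLag latest admissible T-peak after the R-peak, s (default 0.4).
#' @return a [CardiacEvents-class] object.
#' @export
detectTPeaks <- function(ecg, rPeaks, template, sfreq, corrThreshold = 0.6,
                         maxLag = 0.4) {
  if (!length(rPeaks)) {
    warning("no R-peaks supplied; returning an empty event set")
    return(new("CardiacEvents", rTimes = numeric(0), tTimes = numeric(0),
               valid = logical(0), exclusionReason = character(0)))
  }
  r <- .slidingCorr(ecg, template)
  ep <- .corrEpisodes(r, corrThreshold)
  peakIdx <- if (nrow(ep)) .episodePeaks(ecg, ep, template) else integer(0)
  peakT <- (peakIdx - 1L) / sfreq
  peakCorr <- if (nrow(ep))
    vapply(seq_len(nrow(ep)), function(k) max(r[ep[k, 1]:ep[k, 2]]),
           numeric(1)) else numeric(0)
  n <- length(rPeaks)
  tT <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    cand <- which(peakT > rPeaks[i] & peakT <= rPeaks[i] + maxLag)
    if (length(cand)) tT[i] <- peakT[cand[which.max(peakCorr[cand])]]
  }
  found <- !is.na(tT)
  new("CardiacEvents", rTimes = rPeaks, tTimes = tT, valid = found,
      exclusionReason = ifelse(found, "none", "no_t_found"))
}

#' Flag beats in noisy segments or adjacent to extrasystoles
#'
#' Marks as excluded (i) beats inside user-supplied noisy intervals
#' (overlapping intervals are merged, with a message) and (ii) beats
#' flanking an abnormal interbeat interval — one deviating from the running
#' median IBI by more than `extrasystoleFraction`. The extrasystole
#' criterion (default 30% of the running median) is a configurable
#' convention.
#'
#' @param events a [CardiacEvents-class] object.
#' @param noisyIntervals two-column matrix of (start, end) times, s, or NULL.
#' @param extrasystoleFraction maximal tolerated relative IBI deviation.
#' @param medianWindow odd window length (in beats) of the running median.
#' @return the events with updated validity flags and reasons.
#' @export
flagInvalidBeats <- function(events, noisyIntervals = NULL,
                             extrasystoleFraction = 0.30, medianWindow = 9) {
  rT <- events@rTimes
  n <- length(rT)
  valid <- events@valid
  reason <- events@exclusionReason
  if (n >= 3 && extrasystoleFraction > 0) {
    ibi <- diff(rT)
    k <- min(medianWindow, length(ibi))
    if (k %% 2 == 0) k <- k - 1
    med <- if (k >= 3) stats::runmed(ibi, k, endrule = "median")
           else rep(stats::median(ibi), length(ibi))
    abnormal <- abs(ibi - med) / med > extrasystoleFraction
    for (j in which(abnormal)) {
      for (b in c(j, j + 1L)) {
        if (valid[b]) { valid[b] <- FALSE; reason[b] <- "extrasystole_adjacent" }
      }
    }
  }
  if (!is.null(noisyIntervals) && nrow(noisyIntervals)) {
    merged <- mergeIntervals(noisyIntervals)
    if (nrow(merged) < nrow(noisyIntervals))
      message("overlapping noisy intervals merged (",
              nrow(noisyIntervals), " -> ", nrow(merged), ")")
    hit <- inAnyInterval(rT, merged)
    valid[hit] <- FALSE
    reason[hit] <- "noisy_segment"
  }
  new("CardiacEvents", rTimes = rT, tTimes = events@tTimes,
      valid = valid, exclusionReason = reason)
}

#' Full ECG event detection pipeline for one recording
#'
#' Band-pass filters the chosen ECG lead (0.5-40 Hz), builds subject
#' templates, detects R- then T-peaks, and flags invalid beats.
#'
#' @param recording a [Recording-class] (needs an `ECG_<lead>` aux trace) or
#'   a plain numeric ECG trace.
#' @param lead ECG lead name (default `"II"`).
#' @param sfreq sampling rate; taken from the recording when omitted.
#' @param rThreshold,tThreshold correlation thresholds.
#' @param noisyIntervals optional noisy-time intervals, s.
#' @param extrasystoleFraction see [flagInvalidBeats()].
#' @return a [CardiacEvents-class] object.
#' @examples
#' sim <- simulateECG(simulationConfig(seed = 4), duration = 30)
#' ev <- detectCardiacEvents(sim$ecg$II, sfreq = sim$sfreq)
#' @export
detectCardiacEvents <- function(recording, lead = "II", sfreq = NULL,
                                rThreshold = 0.7, tThreshold = 0.6,
                                noisyIntervals = NULL,
                                extrasystoleFraction = 0.30) {
  if (is(recording, "Recording")) {
    ecg <- auxTrace(recording, paste0("ECG_", lead))
    sfreq <- sfreq(recording)
  } else {
    ecg <- as.numeric(recording)
    if (is.null(sfreq)) stop("sfreq required for a plain trace")
  }
  ecg <- butterFilter(ecg, sfreq, low = 0.5, high = 40)
  rtpl <- qrsTemplate(ecg, sfreq, corrThreshold = rThreshold)
  rPeaks <- detectRPeaks(ecg, rtpl, sfreq, rThreshold)
  if (length(rPeaks) < 3)
    return(new("CardiacEvents", rTimes = rPeaks,
               tTimes = rep(NA_real_, length(rPeaks)),
               valid = rep(FALSE, length(rPeaks)),
               exclusionReason = rep("no_t_found", length(rPeaks))))
  ttpl <- tTemplate(ecg, sfreq, rPeaks)
  ev <- detectTPeaks(ecg, rPeaks, ttpl, sfreq, tThreshold)
  flagInvalidBeats(ev, noisyIntervals, extrasystoleFraction)
}

#' Interbeat-interval summary within a time window
#'
#' IBI is the mean successive T-to-T distance among valid T-peaks inside
#' the window; HRV is the sample (n-1) standard deviation of those
#' distances. Requires at least 2 T-peaks for the IBI and 3 for the HRV;
#' otherwise the corresponding value is NA with a reason. Both are
#' invariant to a uniform time translation of all peaks.
#'
#' @param events a [CardiacEvents-class] object.
#' @param window numeric (start, end), s.
#' @return a [CardiacSummary-class] object (values in ms).
#' @examples
#' ev <- new("CardiacEvents", rTimes = c(.7, 1.5, 2.3) - .28,
#'           tTimes = c(.7, 1.5, 2.3), valid = rep(TRUE, 3),
#'           exclusionReason = rep("none", 3))
#' cardiacSummary(ev, c(0, 3))
#' @export
cardiacSummary <- function(events, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  tt <- events@tTimes[events@valid & !is.na(events@tTimes)]
  tt <- sort(tt[tt >= window[1] & tt <= window[2]])
  nB <- length(tt)
  if (nB < 2)
    return(new("CardiacSummary", ibiMean = NA_real_, hrv = NA_real_,
               nBeats = as.integer(nB), reason = "fewer than 2 T-peaks in window"))
  ibis <- diff(tt) * 1000
  hrv <- if (nB >= 3) stats::sd(ibis) else NA_real_
  reason <- if (nB >= 3) "ok" else "fewer than 3 T-peaks: no HRV"
  new("CardiacSummary", ibiMean = mean(ibis), hrv = hrv,
      nBeats = as.integer(nB), reason = reason)
}
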