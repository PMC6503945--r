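# Artifact-component selection (cardiac via pairwise phase consistency with
# the ECG, blink via EOG correlation) and pupil preprocessing.
#
# The source-separation step itself (ICA or similar) is a pluggable input:
# this module consumes component traces (components x time) and owns only
# the selection logic.

#' Pairwise phase consistency between a component and the ECG
#'
#' Epochs both traces from -0.2 to +0.2 s around each R-peak, estimates the
#' phase of each epoch per frequency bin with a single Hann-tapered Fourier
#' transform, and computes the pairwise phase consistency of the
#' component-minus-ECG relative phase:
#' \deqn{PPC = \frac{2}{N(N-1)} \sum_{j<k} \cos(\theta_j - \theta_k)}
#' evaluated per bin in `band` and averaged over bins. PPC is a bias-free
#' phase-coupling statistic: 0 expected under independent phases, 1 for
#' perfectly consistent relative phase. It is invariant to component
#' amplitude scaling and to a constant phase offset common to all epochs.
#'
#' @param componentTrace component time course.
#' @param ecgTrace ECG trace (same sampling).
#' @param rTimes R-peak times, s.
#' @param sfreq sampling frequency, Hz.
#' @param band frequency band, Hz (default 0-25).
#' @return mean PPC across bins (dimensionless, in [-1, 1]).
#' @export
ppcScore <- function(componentTrace, ecgTrace, rTimes, sfreq,
                     band = c(0, 25)) {
  if (band[2] > sfreq / 2) stop("band exceeds the Nyquist frequency")
  half <- round(0.2 * sfreq)
  n <- length(componentTrace)
  idx0 <- round(rTimes * sfreq) + 1L
  idx0 <- idx0[idx0 - half >= 1 & idx0 + half - 1 <= n]
  N <- length(idx0)
  if (N < 2) stop("need at least 2 artifact-free R-locked epochs")
  L <- 2L * half
  taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / (L - 1))  # Hann
  freqs <- (seq_len(L) - 1) / L * sfreq
  bins <- which(freqs > 0 & freqs <= band[2] & freqs >= band[1])
  if (!length(bins)) stop("no frequency bins inside the requested band")
  phases <- matrix(0, N, length(bins))
  for (j in seq_len(N)) {
    sl <- (idx0[j] - half):(idx0[j] + half - 1L)
    fc <- stats::fft(componentTrace[sl] * taper)[bins]
    fe <- stats::fft(ecgTrace[sl] * taper)[bins]
    phases[j, ] <- Arg(fc * Conj(fe))
  }
  ppcPerBin <- vapply(seq_along(bins), function(b) {
    s <- sum(exp(1i * phases[, b]))
    (Mod(s)^2 - N) / (N * (N - 1))
  }, numeric(1))
  mean(ppcPerBin)
}

# Iterative outlier selection: repeatedly remove the component whose score
# exceeds mean + nSd * SD of the *current* (post-removal) set, until no
# outlier remains or `cap` components were removed.
.iterativeOutliers <- function(scores, nSd, cap) {
  ids <- seq_along(scores)
  selected <- integer(0)
  iteration <- integer(0)
  it <- 0L
  while (length(selected) < cap && length(ids) >= 2) {
    cur <- scores[ids]
    bound <- mean(cur) + nSd * stats::sd(cur)
    if (!is.finite(bound)) break
    over <- ids[cur > bound]
    if (!length(over)) break
    it <- it + 1L
    worst <- over[which.max(scores[over])]
    selected <- c(selected, worst)
    iteration <- c(iteration, it)
    ids <- setdiff(ids, worst)
  }
  list(selected = selected, iteration = iteration)
}

#' Select cardiac artifact components by PPC outlier rule
#'
#' Iteratively removes the component whose PPC with the ECG exceeds the
#' mean + 2 SD of the current component set, recomputing mean and SD after
#' each removal, until no outlier remains or two components (the cap) have
#' been selected.
#'
#' @param scores numeric vector of per-component PPC scores (>= 3 components).
#' @param nSd outlier threshold in SDs (default 2).
#' @param cap maximal number of components to select (default 2).
#' @return data.frame with `component`, `score`, `selected`, `iteration`
#'   (0 for unselected components).
#' @examples
#' selectCardiacComponents(c(0.02, -0.01, 0.03, 0.9))
#' @export
selectCardiacComponents <- function(scores, nSd = 2, cap = 2) {
  stopifnot(length(scores) >= 3)
  res <- .iterativeOutliers(scores, nSd, cap)
  out <- data.frame(component = seq_along(scores), score = scores,
                    selected = FALSE, iteration = 0L)
  out$selected[res$selected] <- TRUE
  out$iteration[res$selected] <- res$iteration
  out
}

#' Select blink components by EOG correlation outlier rule
#'
#' Computes the absolute Pearson correlation of each component time course
#' with the vertical EOG and applies the iterative outlier rule at 3 SD with
#' a cap of three components.
#'
#' @param componentTraces matrix, components x time.
#' @param veogTrace vertical EOG trace.
#' @param nSd outlier threshold in SDs (default 3).
#' @param cap maximal number of components to select (default 3).
#' @return data.frame with `component`, `eogCorr`, `selected`, `iteration`.
#' @export
selectBlinkComponents <- function(componentTraces, veogTrace, nSd = 3,
                                  cap = 3) {
  stopifnot(is.matrix(componentTraces),
            ncol(componentTraces) == length(veogTrace),
            nrow(componentTraces) >= 3)
  corr <- abs(apply(componentTraces, 1, stats::cor, y = veogTrace))
  res <- .iterativeOutliers(corr, nSd, cap)
  out <- data.frame(component = seq_len(nrow(componentTraces)),
                    eogCorr = corr, selected = FALSE, iteration = 0L)
  out$selected[res$selected] <- TRUE
  out$iteration[res$selected] <- res$iteration
  out
}

#' Remove selected components from sensor data
#'
#' Given a mixing matrix (channels x components) and component traces
#' (components x time), subtracts the selected components' contribution
#' from the sensor data.
#'
#' @param data channels x samples sensor matrix.
#' @param mixing channels x components mixing matrix.
#' @param componentTraces components x samples matrix.
#' @param selected integer indices of components to remove.
#' @return cleaned data matrix.
#' @export
removeComponents <- function(data, mixing, componentTraces, selected) {
  if (!length(selected)) return(data)
  data - mixing[, selected, drop = FALSE] %*%
    componentTraces[selected, , drop = FALSE]
}

#' Preprocess a pupil trace into imagination-period epochs
#'
#' Blink intervals are extended by 80 ms on both sides; noise intervals are
#' any 300 ms window whose signal range (max - min) exceeds 1 arbitrary
#' unit; the union of both is linearly interpolated; the trace is low-pass
#' filtered at 10 Hz (4th-order zero-phase Butterworth); epochs are cut 2-4
#' s after each imagination onset; epochs with more than 30% interpolated
#' samples (or incomplete coverage) are dropped; survivors are z-scored.
#'
#' @param trace pupil diameter trace, arbitrary units.
#' @param sfreq sampling frequency, Hz.
#' @param blinkIntervals two-column matrix of blink (start, end) times, s.
#' @param trials trial table with `imagination_onset`.
#' @param extend blink extension, s (default 0.08).
#' @param noiseRange range threshold in a.u. (default 1).
#' @param noiseWindow noise detection window, s (default 0.3).
#' @param lowpass low-pass corner, Hz (default 10).
#' @param epochWindow epoch limits relative to imagination onset, s.
#' @param maxInterpolated maximal tolerated interpolated fraction.
#' @return a [PupilEpochs-class] object.
#' @export
preprocessPupil <- function(trace, sfreq, blinkIntervals, trials,
                            extend = 0.08, noiseRange = 1,
                            noiseWindow = 0.3, lowpass = 10,
                            epochWindow = c(2, 4), maxInterpolated = 0.30) {
  n <- length(trace)
  mask <- rep(FALSE, n)                      # samples to interpolate
  if (!is.null(blinkIntervals) && nrow(blinkIntervals)) {
    ext <- cbind(pmax(blinkIntervals[, 1] - extend, 0),
                 blinkIntervals[, 2] + extend)
    for (k in seq_len(nrow(ext))) {
      i0 <- max(1L, floor(ext[k, 1] * sfreq) + 1L)
      i1 <- min(n, ceiling(ext[k, 2] * sfreq))
      mask[i0:i1] <- TRUE
    }
  }
  w <- max(2L, round(noiseWindow * sfreq))
  if (n >= w) {
    rng <- runningMax(trace, w) - runningMin(trace, w)
    bad <- which(rng > noiseRange)           # window start indices
    for (s in bad) mask[s:(s + w - 1L)] <- TRUE
  }
  clean <- trace
  if (any(mask) && !all(mask)) {
    good <- which(!mask)
    clean[mask] <- stats::approx(good, trace[good], xout = which(mask),
                                 rule = 2)$y
  }
  clean <- butterFilter(clean, sfreq, low = NULL, high = lowpass)

  nT <- nrow(trials)
  eLen <- round((epochWindow[2] - epochWindow[1]) * sfreq)
  times <- epochWindow[1] + (seq_len(eLen) - 1L) / sfreq
  epochs <- matrix(NA_real_, nT, eLen)
  frac <- rep(NA_real_, nT)
  retained <- rep(FALSE, nT)
  for (i in seq_len(nT)) {
    i0 <- round((trials$imagination_onset[i] + epochWindow[1]) * sfreq) + 1L
    idx <- i0:(i0 + eLen - 1L)
    if (idx[1] < 1 || idx[eLen] > n) { frac[i] <- 1; next }  # no coverage
    epochs[i, ] <- clean[idx]
    frac[i] <- mean(mask[idx])
    retained[i] <- frac[i] <= maxInterpolated
  }
  for (i in which(retained)) epochs[i, ] <- zscore(epochs[i, ], "pupil epoch")
  new("PupilEpochs", epochs = epochs, times = times,
      interpolatedFraction = frac, retained = retained,
      trialIds = as.integer(trials$trial))
}

#' Flag subjects with too few retained epochs
#'
#' Subjects whose retained-epoch count falls below the group mean minus
#' `nSd` standard deviations are flagged for exclusion.
#'
#' @param counts integer vector of retained-epoch counts, one per subject.
#' @param nSd threshold (default 1.5).
#' @return logical vector, TRUE = flagged.
#' @export
flagLowRetention <- function(counts, nSd = 1.5) {
  counts < mean(counts) - nSd * stats::sd(counts)
}
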