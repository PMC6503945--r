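#' @import methods
NULL

# ---------------------------------------------------------------------------
# Simulation configuration
# ---------------------------------------------------------------------------

#' Simulation configuration for synthetic HER sessions
#'
#' Holds every tunable parameter of the synthetic session generator: cardiac
#' renewal statistics, trial timing ranges, the planted heartbeat-evoked
#' effect (sensors, latency window, per-condition amplitude), the
#' cardiac-field artifact mixing gain, sensor noise, and the rating
#' distributions for the two imagination conditions (Self / Other).
#'
#' All timing parameters are specified in seconds or milliseconds as noted,
#' never in samples, so the same configuration is valid at any sampling rate.
#'
#' @slot seed integer RNG seed for the session.
#' @slot sfreq sampling frequency, Hz.
#' @slot nChannels number of sensor channels.
#' @slot nTrialsPerCondition trials per condition (default 36).
#' @slot ibiMean,ibiSd interbeat-interval mean and SD, ms (defaults 854, 50).
#' @slot imaginationRange imagination-period duration range, s (default 6.7-7.3).
#' @slot fixationRange fixation duration range, s.
#' @slot instructionDuration instruction screen duration, s.
#' @slot responseDuration rating-response period, s.
#' @slot itiRange inter-trial interval range, s.
#' @slot rToTLag lag from R-peak to T-peak apex, ms (default 280).
#' @slot effectSensors channel labels carrying the planted effect
#'   (length 0 = pick a posterior patch of 8 automatically).
#' @slot effectWindow planted-effect latency window after the T-peak, ms.
#' @slot effectAmplitudeSelf,effectAmplitudeOther planted HER amplitude per
#'   condition, sensor units.
#' @slot cardiacArtifactGain overall gain of the cardiac-field artifact
#'   mixed into the sensors.
#' @slot sensorNoiseSd sensor noise SD, sensor units.
#' @slot ecgNoiseSd additive band-limited ECG noise SD (R amplitude is 1).
#' @slot arousalMeanSelf,arousalMeanOther mean arousal rating per condition
#'   on the 1-5 scale (defaults 3.4, 3.0).
#' @slot ratingSd SD of the latent Gaussian behind the discretized ratings.
#' @slot driftAmplitude amplitude of a slow, condition-dependent drift added
#'   over the imagination period of Self trials (not heartbeat-locked; used
#'   to probe the specificity of the surrogate-heartbeat control). 0 = off.
#'
#' @seealso [simulationConfig()], [simulateSession()]
#' @export
setClass("SimulationConfig",
  representation(
    seed = "integer", sfreq = "numeric", nChannels = "integer",
    nTrialsPerCondition = "integer",
    ibiMean = "numeric", ibiSd = "numeric",
    imaginationRange = "numeric", fixationRange = "numeric",
    instructionDuration = "numeric", responseDuration = "numeric",
    itiRange = "numeric",
    rToTLag = "numeric",
    effectSensors = "character", effectWindow = "numeric",
    effectAmplitudeSelf = "numeric", effectAmplitudeOther = "numeric",
    cardiacArtifactGain = "numeric", sensorNoiseSd = "numeric",
    ecgNoiseSd = "numeric",
    arousalMeanSelf = "numeric", arousalMeanOther = "numeric",
    ratingSd = "numeric", driftAmplitude = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@ibiMean <= 0) msg <- c(msg, "ibiMean must be > 0")
  if (object@ibiSd < 0) msg <- c(msg, "ibiSd must be >= 0")
  if (object@ibiSd >= object@ibiMean)
    msg <- c(msg, "ibiSd must be < ibiMean (degenerate renewal process)")
  if (object@sfreq <= 0) msg <- c(msg, "sfreq must be > 0")
  rng <- function(x, nm) {
    if (length(x) != 2 || x[1] > x[2] || any(x <= 0))
      c(msg, sprintf("%s must be positive and ordered (lo <= hi)", nm))
    else msg
  }
  msg <- rng(object@imaginationRange, "imaginationRange")
  msg <- rng(object@fixationRange, "fixationRange")
  msg <- rng(object@itiRange, "itiRange")
  if (object@instructionDuration <= 0 || object@responseDuration < 0)
    msg <- c(msg, "durations must be positive")
  ew <- object@effectWindow
  if (length(ew) != 2 || ew[1] > ew[2] || ew[1] < 80 || ew[2] > 350)
    msg <- c(msg, "effectWindow must lie within [80, 350] ms after the T-peak")
  if (object@rToTLag <= 0 || object@rToTLag > 400)
    msg <- c(msg, "rToTLag must be in (0, 400] ms")
  if (object@nChannels < 1) msg <- c(msg, "nChannels must be >= 1")
  if (object@nTrialsPerCondition < 1)
    msg <- c(msg, "nTrialsPerCondition must be >= 1")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Ground truth
# ---------------------------------------------------------------------------

#' Ground truth of a synthetic session
#'
#' Oracle object recording what the generator actually planted: the true R-
#' and T-peak times, the sensors and latency window of the planted
#' heartbeat-evoked effect, and (when a pupil trace was generated) the blink
#' intervals. Used by tests to score peak detection and cluster recovery;
#' never consumed by the analysis path.
#'
#' @slot rTimes,tTimes true R-peak / T-peak times, s (aligned one-to-one).
#' @slot effectSensors channel labels of the planted effect.
#' @slot effectWindow planted latency window, ms after the T-peak.
#' @slot blinkIntervals two-column matrix of blink (start, end) times, s.
#' @export
setClass("GroundTruth",
  representation(
    rTimes = "numeric", tTimes = "numeric",
    effectSensors = "character", effectWindow = "numeric",
    blinkIntervals = "matrix"
  )
)

setValidity("GroundTruth", function(object) {
  if (length(object@rTimes) != length(object@tTimes))
    return("rTimes and tTimes must be aligned one-to-one")
  lag <- object@tTimes - object@rTimes
  if (length(lag) && (any(lag <= 0) || any(lag > 0.4)))
    return("every T-peak must lie within (0, 400] ms after its R-peak")
  TRUE
})

# ---------------------------------------------------------------------------
# Recording
# ---------------------------------------------------------------------------

#' Continuous multichannel recording
#'
#' Sensor data as a channels x samples matrix plus sampling rate, channel
#' labels, channel positions (3D coordinates with a 2D layout projection),
#' and named auxiliary traces (ECG leads, vertical EOG, EMG, pupil).
#'
#' @slot data numeric matrix, channels x samples.
#' @slot sfreq sampling frequency, Hz.
#' @slot channelLabels character vector, one label per row of `data`.
#' @slot channelPositions numeric matrix with columns x, y, z, layout2d_x,
#'   layout2d_y; one row per channel.
#' @slot aux named list of numeric vectors, each `ncol(data)` long.
#' @export
setClass("Recording",
  representation(
    data = "matrix", sfreq = "numeric",
    channelLabels = "character", channelPositions = "matrix",
    aux = "list"
  )
)

setValidity("Recording", function(object) {
  msg <- character()
  if (object@sfreq <= 0) msg <- c(msg, "sfreq must be > 0")
  n <- nrow(object@data)
  if (n > 0 && length(object@channelLabels) != n)
    msg <- c(msg, "one channel label per data row required")
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, "channel labels must be unique")
  if (n > 0 && nrow(object@channelPositions) != n)
    msg <- c(msg, "one position row per channel required")
  if (n > 0 && anyDuplicated(object@channelPositions[, 1:3, drop = FALSE]))
    msg <- c(msg, "channel positions must be unique")
  if (anyNA(object@data)) msg <- c(msg, "data must not contain NAs")
  ns <- if (n > 0) ncol(object@data) else NA_integer_
  for (nm in names(object@aux)) {
    if (!is.numeric(object@aux[[nm]]))
      msg <- c(msg, sprintf("aux trace '%s' must be numeric", nm))
    else if (!is.na(ns) && length(object@aux[[nm]]) != ns)
      msg <- c(msg, sprintf("aux trace '%s' length must match data", nm))
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Cardiac events and summary
# ---------------------------------------------------------------------------

#' Validated cardiac events
#'
#' R-peak times with their one-to-one T-peak times (NA when no qualifying
#' T-episode was found within 0.4 s of the R-peak), a per-beat validity flag
#' and the exclusion reason.
#'
#' @slot rTimes strictly increasing R-peak times, s.
#' @slot tTimes T-peak times, s; `NA` where no T-peak qualified.
#' @slot valid logical per beat.
#' @slot exclusionReason character per beat, one of `"none"`,
#'   `"noisy_segment"`, `"extrasystole_adjacent"`, `"no_t_found"`.
#' @export
setClass("CardiacEvents",
  representation(
    rTimes = "numeric", tTimes = "numeric",
    valid = "logical", exclusionReason = "character"
  )
)

.exclusionReasons <- c("none", "noisy_segment", "extrasystole_adjacent", "no_t_found")

setValidity("CardiacEvents", function(object) {
  msg <- character()
  n <- length(object@rTimes)
  if (n > 1 && any(diff(object@rTimes) <= 0))
    msg <- c(msg, "rTimes must be strictly increasing")
  if (length(object@tTimes) != n || length(object@valid) != n ||
      length(object@exclusionReason) != n)
    msg <- c(msg, "per-beat slots must all have the same length")
  ok <- !is.na(object@tTimes)
  lag <- object@tTimes[ok] - object@rTimes[seq_len(n)[ok]]
  if (length(lag) && (any(lag <= 0) || any(lag > 0.4 + 1e-9)))
    msg <- c(msg, "each tTime must lie in (rTime, rTime + 0.4 s]")
  if (!all(object@exclusionReason %in% .exclusionReasons))
    msg <- c(msg, "unknown exclusion reason")
  if (any(!object@valid & object@exclusionReason == "none"))
    msg <- c(msg, "excluded beats must carry a reason")
  if (length(msg)) msg else TRUE
})

#' Interbeat-interval summary
#'
#' @slot ibiMean mean successive T-to-T distance, ms (NA if < 2 T-peaks).
#' @slot hrv sample standard deviation (n-1) of the interbeat intervals,
#'   ms (NA if < 3 T-peaks).
#' @slot nBeats number of valid T-peaks in the window.
#' @slot reason why a value is missing, or `"ok"`.
#' @export
setClass("CardiacSummary",
  representation(ibiMean = "numeric", hrv = "numeric",
                 nBeats = "integer", reason = "character"))

setValidity("CardiacSummary", function(object) {
  msg <- character()
  if (!is.na(object@ibiMean) && object@ibiMean <= 0)
    msg <- c(msg, "ibiMean must be > 0")
  if (!is.na(object@hrv) && object@hrv < 0) msg <- c(msg, "hrv must be >= 0")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Pupil epochs
# ---------------------------------------------------------------------------

#' Preprocessed pupil epochs
#'
#' @slot epochs numeric matrix, epochs x time; retained rows are z-scored.
#' @slot times time axis, s relative to imagination onset.
#' @slot interpolatedFraction fraction of interpolated samples per epoch.
#' @slot retained logical per epoch (interpolated fraction <= 0.30 and
#'   fully covered by the trace).
#' @slot trialIds trial index per epoch.
#' @export
setClass("PupilEpochs",
  representation(epochs = "matrix", times = "numeric",
                 interpolatedFraction = "numeric", retained = "logical",
                 trialIds = "integer"))

setValidity("PupilEpochs", function(object) {
  msg <- character()
  n <- nrow(object@epochs)
  if (length(object@interpolatedFraction) != n || length(object@retained) != n ||
      length(object@trialIds) != n)
    msg <- c(msg, "per-epoch slots must match the number of epoch rows")
  if (any(object@retained & object@interpolatedFraction > 0.30 + 1e-12))
    msg <- c(msg, "retained epochs must have interpolated fraction <= 0.30")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# HER epochs and averages
# ---------------------------------------------------------------------------

#' Heartbeat-locked epochs
#'
#' T-peak-locked sensor epochs as a heartbeats x channels x time tensor,
#' spanning -100 to +400 ms around each T-peak, with per-epoch trial
#' membership and condition labels inherited from the trial table.
#'
#' @slot data numeric array, heartbeats x channels x time.
#' @slot times time axis, ms relative to the T-peak (spans [-100, 400]).
#' @slot channelLabels channel labels matching the source recording.
#' @slot epochInfo data.frame with one row per epoch: `trial`, `condition`,
#'   `tTime` (s, absolute).
#' @slot sfreq sampling frequency, Hz.
#' @slot dropLog data.frame of rejected candidate epochs (`trial`, `tTime`,
#'   `reason`).
#' @export
setClass("HEREpochs",
  representation(data = "array", times = "numeric",
                 channelLabels = "character", epochInfo = "data.frame",
                 sfreq = "numeric", dropLog = "data.frame"),
  prototype(dropLog = data.frame(trial = integer(0), tTime = numeric(0),
                                 reason = character(0))))

setValidity("HEREpochs", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3) return("data must be a 3-D array (beats x channels x time)")
  if (length(object@times) != d[3]) msg <- c(msg, "times must match the 3rd dim")
  if (length(object@channelLabels) != d[2])
    msg <- c(msg, "channelLabels must match the 2nd dim")
  if (nrow(object@epochInfo) != d[1])
    msg <- c(msg, "epochInfo must have one row per epoch")
  if (d[3] > 0 && (min(object@times) > 80 || max(object@times) < 350))
    msg <- c(msg, "the [80, 350] ms analysis window must be a strict sub-span")
  if (d[1] > 0 && !all(c("trial", "condition", "tTime") %in% names(object@epochInfo)))
    msg <- c(msg, "epochInfo needs columns trial, condition, tTime")
  if (length(msg)) msg else TRUE
})

#' Condition-wise HER averages
#'
#' @slot averages named list (one entry per condition) of channels x time
#'   mean waveforms.
#' @slot nEpochs named integer vector of epochs entering each average.
#' @slot times time axis, ms relative to the T-peak.
#' @slot channelLabels channel labels.
#' @export
setClass("HERAverage",
  representation(averages = "list", nEpochs = "integer",
                 times = "numeric", channelLabels = "character"))

setValidity("HERAverage", function(object) {
  if (any(object@nEpochs <= 0))
    return("each averaged condition must contain at least one epoch")
  if (!identical(names(object@averages), names(object@nEpochs)))
    return("averages and nEpochs must be aligned by condition name")
  TRUE
})

# ---------------------------------------------------------------------------
# Sensor adjacency and cluster statistics
# ---------------------------------------------------------------------------

#' Sensor adjacency (neighbor lists)
#'
#' Symmetric spatial neighborhood structure over channels, stored as integer
#' neighbor lists keyed by channel label. Works for planar sensor layouts
#' and for arbitrary graphs (e.g. cortical meshes).
#'
#' @slot neighbors named list; element i holds the integer indices of the
#'   neighbors of channel i.
#' @slot labels channel labels (names of `neighbors`).
#' @export
setClass("SensorAdjacency",
  representation(neighbors = "list", labels = "character"))

setValidity("SensorAdjacency", function(object) {
  n <- length(object@labels)
  if (length(object@neighbors) != n)
    return("one neighbor list per channel required")
  for (i in seq_len(n)) {
    nb <- object@neighbors[[i]]
    if (any(nb == i)) return("self-loops are not allowed")
    if (any(nb < 1 | nb > n)) return("neighbor index out of range")
    for (j in nb) if (!(i %in% object@neighbors[[j]]))
      return("adjacency must be symmetric")
  }
  TRUE
})

#' Spatio-temporal t-map
#'
#' @slot t numeric matrix of per-sample paired t statistics, channels x time.
#' @slot df degrees of freedom (n subjects - 1).
#' @slot firstLevelAlpha two-tailed first-level threshold used downstream.
#' @export
setClass("SpatioTemporalTMap",
  representation(t = "matrix", df = "numeric", firstLevelAlpha = "numeric"))

setValidity("SpatioTemporalTMap", function(object) {
  if (any(!is.finite(object@t))) return("t-values must be finite")
  if (object@df < 1) return("df must be >= 1")
  TRUE
})

#' Result of the spatio-temporal cluster permutation test
#'
#' @slot clusters list of clusters; each is a list with `members` (two-column
#'   matrix of channel/time indices), `channels` (labels), `sumT`, `sign`
#'   (+1/-1), `p` (plain Monte-Carlo proportion for its tail), `significant`
#'   (tail tested at alpha/2, see the methods vignette), and `cohenD`.
#' @slot maxDistribution,minDistribution permutation distributions of the
#'   maximal positive / minimal negative cluster sums (0 when a tail had no
#'   cluster in a permutation).
#' @slot nPermutations number of label permutations.
#' @slot tmap the observed [SpatioTemporalTMap-class].
#' @slot alpha nominal two-tailed test level for the significance flag.
#' @slot params list of clustering parameters (thresholdP, minNeighbors, seed).
#' @export
setClass("ClusterTestResult",
  representation(clusters = "list",
                 maxDistribution = "numeric", minDistribution = "numeric",
                 nPermutations = "integer", tmap = "SpatioTemporalTMap",
                 alpha = "numeric", params = "list"))

setValidity("ClusterTestResult", function(object) {
  msg <- character()
  if (length(object@maxDistribution) != object@nPermutations ||
      length(object@minDistribution) != object@nPermutations)
    msg <- c(msg, "permutation distributions must have length nPermutations")
  for (cl in object@clusters) {
    if (!is.null(cl$p) && (cl$p < 0 || cl$p > 1))
      msg <- c(msg, "cluster p must lie in [0, 1]")
    if (!cl$sign %in% c(-1, 1)) msg <- c(msg, "cluster sign must be +1 or -1")
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Resampling results
# ---------------------------------------------------------------------------

#' Surrogate-heartbeat test result
#'
#' @slot observedMinSumT observed minimal negative cluster sum of t.
#' @slot surrogateMinSums minimal negative cluster sums across surrogates.
#' @slot p fraction of surrogate minima <= the observed minimum.
#' @slot observedMaxSumT,surrogateMaxSums same bookkeeping for the positive
#'   tail, for two-sided use.
#' @slot pAbs fraction of surrogate extremes exceeding the observed extreme
#'   in absolute value (the arithmetic behind "k out of N permutations").
#' @slot nSurrogates number of surrogate timing permutations.
#' @export
setClass("SurrogateResult",
  representation(observedMinSumT = "numeric", surrogateMinSums = "numeric",
                 observedMaxSumT = "numeric", surrogateMaxSums = "numeric",
                 p = "numeric", pAbs = "numeric", nSurrogates = "integer"))

setValidity("SurrogateResult", function(object) {
  if (length(object@surrogateMinSums) != object@nSurrogates)
    return("surrogateMinSums must have length nSurrogates")
  if (object@p < 0 || object@p > 1) return("p must lie in [0, 1]")
  TRUE
})

#' Rating-stratification result
#'
#' @slot retainedA,retainedB indices of retained trials per condition.
#' @slot iterations number of removal iterations performed.
#' @slot finalMeans named numeric, final rating means per condition.
#' @slot converged TRUE when the stopping rule was met before either
#'   condition was exhausted or the iteration cap was hit.
#' @slot relDifference final relative mean difference (vs the mean of the
#'   two condition means), or absolute difference in absolute mode.
#' @export
setClass("StratificationResult",
  representation(retainedA = "integer", retainedB = "integer",
                 iterations = "integer", finalMeans = "numeric",
                 converged = "logical", relDifference = "numeric"))

# ---------------------------------------------------------------------------
# Inference results
# ---------------------------------------------------------------------------

#' Per-subject GLM result
#'
#' @slot beta named numeric vector of OLS coefficients (intercept excluded).
#' @slot regressors regressor names.
#' @slot zScored names of the variables that were z-scored before fitting.
#' @slot n number of trials entering the fit.
#' @export
setClass("GLMResult",
  representation(beta = "numeric", regressors = "character",
                 zScored = "character", n = "integer"))

setValidity("GLMResult", function(object) {
  if (length(object@beta) != length(object@regressors))
    return("one beta per regressor required")
  TRUE
})

#' Bayes factor with evidence label
#'
#' Convention throughout: BF > 1 supports the null hypothesis and BF < 1
#' the alternative.
#'
#' @slot bf the Bayes factor (null over alternative).
#' @slot method one of `"bic_paired"`, `"jzs_correlation"`,
#'   `"jzs_two_sample"`, `"jzs_one_sample"`.
#' @slot label Jeffreys-style verbal category, e.g.
#'   `"substantial evidence for H0"`.
#' @export
setClass("BayesFactorResult",
  representation(bf = "numeric", method = "character", label = "character"))

setValidity("BayesFactorResult", function(object) {
  if (!is.na(object@bf) && object@bf <= 0) return("bf must be > 0")
  TRUE
})

#' Group-level Fisher-z correlation test
#'
#' @slot r per-subject Pearson correlation coefficients.
#' @slot z Fisher-z transformed coefficients.
#' @slot meanR mean correlation across subjects.
#' @slot rSquared squared mean correlation (shared variance).
#' @slot t,p,df one-sample t test of the z values against zero.
#' @export
setClass("GroupCorrelationResult",
  representation(r = "numeric", z = "numeric", meanR = "numeric",
                 rSquared = "numeric", t = "numeric", p = "numeric",
                 df = "numeric"))

setValidity("GroupCorrelationResult", function(object) {
  if (any(abs(object@r) >= 1))
    return("|r| must be < 1 for the Fisher transform")
  TRUE
})
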