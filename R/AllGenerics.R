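# Accessor generics and show methods. Slots are never accessed with @ by
# user code; these accessors are the supported surface.

#' @rdname Recording-class
#' @param object,x an object of the documented class
#' @export
setGeneric("sfreq", function(object) standardGeneric("sfreq"))
#' @rdname Recording-class
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))
#' @rdname Recording-class
#' @export
setGeneric("channelPositions", function(object) standardGeneric("channelPositions"))
#' @rdname Recording-class
#' @export
setGeneric("sensorData", function(object) standardGeneric("sensorData"))
#' @rdname Recording-class
#' @param name auxiliary trace name
#' @export
setGeneric("auxTrace", function(object, name) standardGeneric("auxTrace"))

#' @rdname CardiacEvents-class
#' @param object object
#' @export
setGeneric("rTimes", function(object) standardGeneric("rTimes"))
#' @rdname CardiacEvents-class
#' @export
setGeneric("tTimes", function(object) standardGeneric("tTimes"))
#' @rdname CardiacEvents-class
#' @export
setGeneric("validBeats", function(object) standardGeneric("validBeats"))
#' @rdname CardiacEvents-class
#' @export
setGeneric("exclusionReasons", function(object) standardGeneric("exclusionReasons"))

#' @rdname HEREpochs-class
#' @param object object
#' @export
setGeneric("epochData", function(object) standardGeneric("epochData"))
#' @rdname HEREpochs-class
#' @export
setGeneric("epochInfo", function(object) standardGeneric("epochInfo"))
#' @rdname HEREpochs-class
#' @export
setGeneric("epochTimes", function(object) standardGeneric("epochTimes"))

#' @rdname ClusterTestResult-class
#' @param object object
#' @export
setGeneric("clusters", function(object) standardGeneric("clusters"))
#' @rdname ClusterTestResult-class
#' @export
setGeneric("tMap", function(object) standardGeneric("tMap"))

#' @rdname SensorAdjacency-class
#' @param object object
#' @export
setGeneric("neighborList", function(object) standardGeneric("neighborList"))

#' @rdname BayesFactorResult-class
#' @param object object
#' @export
setGeneric("bayesFactor", function(object) standardGeneric("bayesFactor"))
#' @rdname BayesFactorResult-class
#' @export
setGeneric("evidenceLabel", function(object) standardGeneric("evidenceLabel"))

# -- Recording ---------------------------------------------------------------

#' @rdname Recording-class
#' @export
setMethod("sfreq", "Recording", function(object) object@sfreq)
#' @rdname Recording-class
#' @export
setMethod("channelLabels", "Recording", function(object) object@channelLabels)
#' @rdname Recording-class
#' @export
setMethod("channelPositions", "Recording", function(object) object@channelPositions)
#' @rdname Recording-class
#' @export
setMethod("sensorData", "Recording", function(object) object@data)
#' @rdname Recording-class
#' @export
setMethod("auxTrace", "Recording", function(object, name) {
  if (!name %in% names(object@aux))
    stop("no auxiliary trace named '", name, "'")
  object@aux[[name]]
})

setMethod("show", "Recording", function(object) {
  dur <- if (nrow(object@data)) ncol(object@data) / object@sfreq
         else if (length(object@aux)) length(object@aux[[1]]) / object@sfreq
         else 0
  cat(sprintf("Recording: %d channels, %.1f s at %g Hz\n",
              nrow(object@data), dur, object@sfreq))
  if (length(object@aux))
    cat("  aux traces:", paste(names(object@aux), collapse = ", "), "\n")
})

# -- CardiacEvents -----------------------------------------------------------

#' @rdname CardiacEvents-class
#' @export
setMethod("rTimes", "CardiacEvents", function(object) object@rTimes)
#' @rdname CardiacEvents-class
#' @export
setMethod("tTimes", "CardiacEvents", function(object) object@tTimes)
#' @rdname CardiacEvents-class
#' @export
setMethod("validBeats", "CardiacEvents", function(object) object@valid)
#' @rdname CardiacEvents-class
#' @export
setMethod("exclusionReasons", "CardiacEvents", function(object) object@exclusionReason)
#' @rdname GroundTruth-class
#' @export
setMethod("rTimes", "GroundTruth", function(object) object@rTimes)
#' @rdname GroundTruth-class
#' @export
setMethod("tTimes", "GroundTruth", function(object) object@tTimes)

setMethod("show", "CardiacEvents", function(object) {
  n <- length(object@rTimes)
  cat(sprintf("CardiacEvents: %d beats, %d valid\n", n, sum(object@valid)))
  if (any(!object@valid)) {
    tab <- table(object@exclusionReason[!object@valid])
    cat("  exclusions:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
})

setMethod("show", "CardiacSummary", function(object) {
  cat(sprintf("CardiacSummary: IBI %.1f ms, HRV %.1f ms over %d T-peaks (%s)\n",
              object@ibiMean, object@hrv, object@nBeats, object@reason))
})

# -- HEREpochs / HERAverage --------------------------------------------------

#' @rdname HEREpochs-class
#' @export
setMethod("epochData", "HEREpochs", function(object) object@data)
#' @rdname HEREpochs-class
#' @export
setMethod("epochInfo", "HEREpochs", function(object) object@epochInfo)
#' @rdname HEREpochs-class
#' @export
setMethod("epochTimes", "HEREpochs", function(object) object@times)
#' @rdname HEREpochs-class
#' @export
setMethod("channelLabels", "HEREpochs", function(object) object@channelLabels)
#' @rdname HEREpochs-class
#' @export
setMethod("sfreq", "HEREpochs", function(object) object@sfreq)

setMethod("show", "HEREpochs", function(object) {
  d <- dim(object@data)
  cat(sprintf("HEREpochs: %d heartbeats x %d channels x %d samples (%g to %g ms)\n",
              d[1], d[2], d[3], min(object@times), max(object@times)))
  if (d[1] > 0) {
    tab <- table(object@epochInfo$condition)
    cat("  per condition:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
})

setMethod("show", "HERAverage", function(object) {
  cat("HERAverage over conditions:",
      paste(sprintf("%s (n=%d)", names(object@averages), object@nEpochs),
            collapse = ", "), "\n")
})

# -- Cluster statistics ------------------------------------------------------

#' @rdname SensorAdjacency-class
#' @export
setMethod("neighborList", "SensorAdjacency", function(object) {
  stats::setNames(lapply(object@neighbors, function(i) object@labels[i]),
                  object@labels)
})
#' @rdname SensorAdjacency-class
#' @export
setMethod("channelLabels", "SensorAdjacency", function(object) object@labels)

setMethod("show", "SensorAdjacency", function(object) {
  deg <- lengths(object@neighbors)
  cat(sprintf("SensorAdjacency: %d channels, degree %d-%d (median %g)\n",
              length(object@labels), min(deg), max(deg), stats::median(deg)))
})

#' @rdname ClusterTestResult-class
#' @export
setMethod("clusters", "ClusterTestResult", function(object) object@clusters)
#' @rdname ClusterTestResult-class
#' @export
setMethod("tMap", "ClusterTestResult", function(object) object@tmap@t)

setMethod("show", "SpatioTemporalTMap", function(object) {
  cat(sprintf("SpatioTemporalTMap: %d channels x %d bins, df = %g\n",
              nrow(object@t), ncol(object@t), object@df))
})

setMethod("show", "ClusterTestResult", function(object) {
  cat(sprintf("ClusterTestResult: %d cluster(s), %d permutations\n",
              length(object@clusters), object@nPermutations))
  for (i in seq_along(object@clusters)) {
    cl <- object@clusters[[i]]
    cat(sprintf("  [%d] sign %+d, sum(t) = %.3f, p = %.4g%s, d = %.2f, %d samples\n",
                i, cl$sign, cl$sumT, cl$p,
                if (isTRUE(cl$significant)) " *" else "",
                cl$cohenD, nrow(cl$members)))
  }
})

setMethod("show", "SurrogateResult", function(object) {
  cat(sprintf(
    "SurrogateResult: observed min sum(t) = %.3f, p = %.4g (%d surrogates)\n",
    object@observedMinSumT, object@p, object@nSurrogates))
})

setMethod("show", "StratificationResult", function(object) {
  cat(sprintf(
    "StratificationResult: %s after %d iterations; retained %d + %d trials; means %s (rel. diff %.3g)\n",
    if (object@converged) "converged" else "NOT converged",
    object@iterations, length(object@retainedA), length(object@retainedB),
    paste(sprintf("%s=%.3f", names(object@finalMeans), object@finalMeans),
          collapse = ", "),
    object@relDifference))
})

# -- Inference ---------------------------------------------------------------

setMethod("show", "GLMResult", function(object) {
  cat(sprintf("GLMResult (%d trials):\n", object@n))
  print(round(object@beta, 4))
})

#' @rdname BayesFactorResult-class
#' @export
setMethod("bayesFactor", "BayesFactorResult", function(object) object@bf)
#' @rdname BayesFactorResult-class
#' @export
setMethod("evidenceLabel", "BayesFactorResult", function(object) object@label)

setMethod("show", "BayesFactorResult", function(object) {
  cat(sprintf("BF = %.4g (%s) - %s\n", object@bf, object@method, object@label))
})

setMethod("show", "GroupCorrelationResult", function(object) {
  cat(sprintf(
    "GroupCorrelationResult: mean r = %.3f (r^2 = %.3f), t(%g) = %.3f, p = %.4g\n",
    object@meanR, object@rSquared, object@df, object@t, object@p))
})
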