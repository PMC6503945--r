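# The two bespoke resampling procedures: the surrogate-heartbeat locking
# test and the rating-stratification control.

# Epoch tensor (beats x channels x time) for absolute event times, given a
# pre-filtered channels x samples matrix. Returns NULL when nothing fits.
.epochTensor <- function(dat, sf, times, rel) {
  if (!length(times)) return(NULL)
  i0 <- round(times * sf) + 1L
  ok <- (i0 + rel[1]) >= 1L & (i0 + rel[length(rel)]) <= ncol(dat)
  i0 <- i0[ok]
  if (!length(i0)) return(NULL)
  cols <- as.vector(t(outer(i0, rel, "+")))    # time fastest within beat
  X <- dat[, cols, drop = FALSE]               # ch x (nT * nB)
  aperm(array(X, c(nrow(dat), length(rel), length(i0))), c(3, 1, 2))
}

# Peak-to-peak per (beat, channel) without apply(): Reduce over time slabs.
.ptpMatrix <- function(tensor) {
  slabs <- lapply(seq_len(dim(tensor)[3]), function(t) tensor[, , t])
  if (dim(tensor)[1] == 1)
    slabs <- lapply(slabs, function(x) matrix(x, nrow = 1))
  Reduce(pmax, slabs) - Reduce(pmin, slabs)
}

# Per-subject preparation for the surrogate test: filtered data, rated
# trials and per-trial donor sets of onset-relative eligible beat times
# (beat validity and the next-R rule are properties of the original
# heartbeat sequence and travel with the timing set).
.prepareSurrogateSubject <- function(recording, trials, events,
                                     lowpass, minNextR) {
  sf <- sfreq(recording)
  dat <- sensorData(recording)
  if (!is.null(lowpass)) dat <- butterFilter(dat, sf, low = NULL, high = lowpass)
  rated <-!is.na(trials$perspective) & !is.na(trials$valence) &
    !is.na(trials$arousal) & as.logical(trials$responded)
  tr <- trials[rated, , drop = FALSE]
  rT <- events@rTimes; tT <- events@tTimes
  ok <- events@valid & !is.na(tT)
  tOk <- tT[ok]
  nxt <- findInterval(tOk, rT) + 1L
  gap <- ifelse(nxt <= length(rT), rT[pmin(nxt, length(rT))] - tOk, Inf)
  tOk <- tOk[gap >= minNextR]
  relSets <- lapply(seq_len(nrow(tr)), function(i) {
    sel <- tOk[tOk >= tr$imagination_onset[i] & tOk <= tr$imagination_offset[i]]
    sel - tr$imagination_onset[i]
  })
  list(dat = dat, sf = sf, trials = tr, relSets = relSets,
       dur = tr$imagination_offset - tr$imagination_onset)
}

# Condition-average HER matrices (channels x window bins) for one subject
# under a given donor-to-recipient assignment. The amplitude-artifact rule
# pools epochs across both conditions (channel-wise median peak-to-peak),
# exactly as in extractHEREpochs, so the identity assignment reproduces the
# standard pipeline statistic.
.subjectConditionAverages <- function(prep, assignment, rel, winIdx,
                                      startOffset, endOffset,
                                      artifactMultiple, conditions) {
  nCh <- nrow(prep$dat)
  condOf <- times <- NULL
  for (cond in conditions) {
    rows <- which(prep$trials$condition == cond)
    tt <- unlist(lapply(rows, function(j) {
      relT <- prep$relSets[[assignment[j]]]
      relT <- relT[relT >= startOffset & relT <= prep$dur[j] - endOffset]
      prep$trials$imagination_onset[j] + relT
    }))
    times <- c(times, tt)
    condOf <- c(condOf, rep(cond, length(tt)))
  }
  tensor <- .epochTensor(prep$dat, prep$sf, times, rel)
  if (is.null(tensor)) return(NULL)
  # .epochTensor silently drops edge epochs; realign the labels
  i0 <- round(times * prep$sf) + 1L
  inRange <- (i0 + rel[1]) >= 1L & (i0 + rel[length(rel)]) <= ncol(prep$dat)
  condOf <- condOf[inRange]
  if (is.finite(artifactMultiple) && dim(tensor)[1] > 1) {
    ptp <- .ptpMatrix(tensor)
    medPtp <- apply(ptp, 2, stats::median)
    bad <- rowSums(ptp > matrix(artifactMultiple * medPtp,
                                nrow(ptp), nCh, byrow = TRUE)) > 0
    tensor <- tensor[!bad, , , drop = FALSE]
    condOf <- condOf[!bad]
  }
  res <- stats::setNames(vector("list", 2), conditions)
  for (cond in conditions) {
    sel <- which(condOf == cond)
    if (!length(sel)) return(NULL)
    sub <- tensor[sel, , winIdx, drop = FALSE]
    res[[cond]] <- matrix(colMeans(matrix(sub, nrow = length(sel))),
                          nCh, length(winIdx))
  }
  res
}

#' Surrogate-heartbeat locking test
#'
#' Tests whether a Self-vs-Other HER difference is genuinely locked to
#' heartbeats: within each subject the per-trial sets of heartbeat timings
#' (taken relative to the imagination onset) are randomly reassigned across
#' trials, the standard eligibility and artifact rules are re-applied, the
#' condition-average HERs recomputed, and the minimal negative cluster sum
#' of the group paired t map extracted. A heartbeat-locked effect vanishes
#' under reassignment; a slow condition difference (not locked to
#' heartbeats) survives it, so the observed statistic is only extreme
#' relative to the surrogate distribution in the former case.
#'
#' Surrogate assignments are full random permutations of trial indices
#' (fixed points allowed, the identity excluded). `p` is the fraction of
#' surrogate minimal sums at or below the observed one; `pAbs` compares
#' absolute extremes (the "k out of N permutations more extreme"
#' arithmetic).
#'
#' @param subjects list; one element per subject, each a list with
#'   `recording` (cleaned [Recording-class]), `trials` (trial table) and
#'   `events` ([CardiacEvents-class]).
#' @param adjacency a [SensorAdjacency-class].
#' @param nSurrogates number of timing permutations (default 1000).
#' @param seed RNG seed.
#' @param analysisWindow cluster-statistic window, ms after the T-peak.
#' @param lowpass low-pass corner for the HER data, Hz.
#' @param epochWindow epoch limits relative to the T-peak, s.
#' @param thresholdP,minNeighbors first-level clustering parameters.
#' @param artifactMultiple epoch rejection multiple of the channel median epoch peak-to-peak (Inf = off).
#' @param startOffset,endOffset,minNextR heartbeat eligibility parameters
#'   (see [selectHeartbeats()]).
#' @param conditions the two condition labels, first minus second in the
#'   paired contrast.
#' @return a [SurrogateResult-class] object.
#' @export
surrogateHeartbeatTest <- function(subjects, adjacency, nSurrogates = 1000,
                                   seed = 1, analysisWindow = c(80, 350),
                                   lowpass = 30, epochWindow = c(-0.1, 0.4),
                                   thresholdP = 0.05, minNeighbors = 4,
                                   artifactMultiple = 3,
                                   startOffset = 2, endOffset = 0.4,
                                   minNextR = 0.4,
                                   conditions = c("Self", "Other")) {
  nSub <- length(subjects)
  if (nSub < 2) stop("need at least 2 subjects")
  preps <- lapply(subjects, function(s) {
    if (nrow(s$trials) < 2) stop("fewer than 2 trials for a subject")
    .prepareSurrogateSubject(s$recording, s$trials, s$events,
                             lowpass, minNextR)
  })
  sf <- preps[[1]]$sf
  rel <- seq(round(epochWindow[1] * sf), round(epochWindow[2] * sf))
  timesMs <- rel / sf * 1000
  winIdx <- which(timesMs >= analysisWindow[1] & timesMs <= analysisWindow[2])
  nCh <- length(adjacency@labels)
  nbList <- adjacency@neighbors
  A <- .adjMatrix(adjacency)
  tcrit <- stats::qt(1 - thresholdP / 2, nSub - 1)

  stat <- function(assignments) {
    d <- array(NA_real_, c(nSub, nCh, length(winIdx)))
    for (s in seq_len(nSub)) {
      avg <- .subjectConditionAverages(preps[[s]], assignments[[s]], rel,
                                       winIdx, startOffset, endOffset,
                                       artifactMultiple, conditions)
      if (is.null(avg)) return(NULL)
      d[s, , ] <- avg[[1]] - avg[[2]]
    }
    D <- matrix(d, nrow = nSub)
    tv <- .tFromDiff(colMeans(D), colSums(D^2), nSub)$t
    cl <- .formClustersCore(matrix(tv, nCh, length(winIdx)), nbList, A,
                            tcrit, minNeighbors)
    sums <- vapply(cl, function(x) x$sumT, numeric(1))
    c(min = if (any(sums < 0)) min(sums) else 0,
      max = if (any(sums > 0)) max(sums) else 0)
  }

  identityAssign <- lapply(preps, function(p) seq_len(nrow(p$trials)))
  obs <- stat(identityAssign)
  if (is.null(obs)) stop("observed statistic undefined (no usable epochs)")

  surMin <- numeric(nSurrogates); surMax <- numeric(nSurrogates)
  withSeed(seed, {
    for (k in seq_len(nSurrogates)) {
      assign <- lapply(preps, function(p) {
        nT <- nrow(p$trials)
        repeat {
          perm <- sample.int(nT)
          if (!all(perm == seq_len(nT))) break
        }
        perm
      })
      s <- stat(assign)
      if (is.null(s)) { surMin[k] <- 0; surMax[k] <- 0 }
      else { surMin[k] <- s["min"]; surMax[k] <- s["max"] }
    }
  })
  obsExtreme <- max(abs(obs))
  surExtreme <- pmax(abs(surMin), abs(surMax))
  new("SurrogateResult",
      observedMinSumT = unname(obs["min"]), surrogateMinSums = surMin,
      observedMaxSumT = unname(obs["max"]), surrogateMaxSums = surMax,
      p = mean(surMin <= obs["min"]),
      pAbs = mean(surExtreme >= obsExtreme),
      nSurrogates = as.integer(nSurrogates))
}

#' Iterative rating stratification
#'
#' Equates a per-trial rating between two conditions by iterative trial
#' removal: at each step one condition is selected at random; if its mean
#' rating is larger than the other's, one trial holding its maximum rating
#' is removed (random tie-break), otherwise one trial holding its minimum
#' rating; iteration stops when the mean difference falls below
#' `tolerance`. The same routine serves arousal and emotion-intensity
#' (absolute valence) stratification.
#'
#' The difference is measured relative to the mean of the two condition
#' means (`mode = "relative"`, the default) or absolutely
#' (`mode = "absolute"`). A condition exhausted before convergence, or
#' hitting the iteration cap, yields `converged = FALSE`; the absolute
#' difference of means is not guaranteed to decrease at every step (the
#' condition is drawn at random), only termination is guaranteed by the cap.
#'
#' @param ratingsA,ratingsB per-trial ratings (integers) of the two
#'   conditions.
#' @param tolerance stopping tolerance (default 0.02 = 2%).
#' @param seed RNG seed.
#' @param mode `"relative"` or `"absolute"` difference.
#' @param maxIterations iteration cap (default 10x total trials).
#' @return a [StratificationResult-class] object.
#' @examples
#' stratify(c(5, 3, 3, 3), c(3, 3, 3, 3), seed = 2)
#' @export
stratify <- function(ratingsA, ratingsB, tolerance = 0.02, seed = 1,
                     mode = c("relative", "absolute"),
                     maxIterations = 10 * (length(ratingsA) + length(ratingsB))) {
  mode <- match.arg(mode)
  stopifnot(length(ratingsA) > 0, length(ratingsB) > 0)
  withSeed(seed, {
    keep <- list(a = seq_along(ratingsA), b = seq_along(ratingsB))
    vals <- list(a = ratingsA, b = ratingsB)
    it <- 0L
    converged <- FALSE
    diffMeasure <- function(mA, mB) {
      if (mode == "absolute") abs(mA - mB)
      else abs(mA - mB) / ((mA + mB) / 2)
    }
    repeat {
      mA <- mean(vals$a[keep$a]); mB <- mean(vals$b[keep$b])
      dd <- diffMeasure(mA, mB)
      if (dd < tolerance) { converged <- TRUE; break }
      if (it >= maxIterations) break
      it <- it + 1L
      sel <- sample(c("a", "b"), 1)
      other <- if (sel == "a") "b" else "a"
      mSel <- mean(vals[[sel]][keep[[sel]]])
      mOth <- mean(vals[[other]][keep[[other]]])
      cur <- vals[[sel]][keep[[sel]]]
      target <- if (mSel > mOth) which(cur == max(cur)) else which(cur == min(cur))
      dropPos <- if (length(target) > 1) sample(target, 1) else target
      keep[[sel]] <- keep[[sel]][-dropPos]
      if (!length(keep[[sel]])) break   # condition exhausted
    }
    mA <- if (length(keep$a)) mean(vals$a[keep$a]) else NA_real_
    mB <- if (length(keep$b)) mean(vals$b[keep$b]) else NA_real_
    dd <- if (is.na(mA) || is.na(mB)) NA_real_ else diffMeasure(mA, mB)
    new("StratificationResult",
        retainedA = as.integer(keep$a), retainedB = as.integer(keep$b),
        iterations = it, finalMeans = c(a = mA, b = mB),
        converged = converged && length(keep$a) > 0 && length(keep$b) > 0,
        relDifference = dd)
  })
}
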