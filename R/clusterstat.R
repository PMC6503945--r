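# Spatio-temporal cluster-based permutation test over sensors x time.
# Works unchanged on arbitrary graphs (vertex adjacency), so the same engine
# serves sensor grids and cortical meshes.

# t statistics from a subjects x P difference matrix. Zero-variance columns
# yield t = 0 (flagged by the caller).
.tFromDiff <- function(m, ss, n) {
  v <- pmax(ss - n * m^2, 0) / (n - 1)
  tv <- ifelse(v > 0, m / sqrt(v / n), 0)
  list(t = tv, zeroVar = v <= 0)
}

#' Per-sample paired t map
#'
#' Computes the paired t statistic per (channel, time) sample between two
#' matched subject x channel x time arrays. Samples with zero-variance
#' differences get t = 0 with a warning.
#'
#' @param a,b numeric arrays, subjects x channels x time, matched by
#'   subject along the first dimension.
#' @param firstLevelAlpha two-tailed first-level threshold recorded for
#'   downstream clustering (default 0.05).
#' @return a [SpatioTemporalTMap-class] with df = n subjects - 1.
#' @export
pairedTMap <- function(a, b, firstLevelAlpha = 0.05) {
  stopifnot(identical(dim(a), dim(b)), length(dim(a)) == 3)
  n <- dim(a)[1]
  if (n < 2) stop("need at least 2 subjects")
  D <- matrix(a - b, nrow = n)
  res <- .tFromDiff(colMeans(D), colSums(D^2), n)
  if (any(res$zeroVar))
    warning("zero-variance differences at ", sum(res$zeroVar),
            " sample(s); t set to 0")
  tm <- matrix(res$t, dim(a)[2], dim(a)[3])
  new("SpatioTemporalTMap", t = tm, df = n - 1,
      firstLevelAlpha = firstLevelAlpha)
}

# Dense 0/1 adjacency matrix from a SensorAdjacency.
.adjMatrix <- function(adjacency) {
  n <- length(adjacency@labels)
  A <- matrix(0L, n, n)
  for (i in seq_len(n)) A[i, adjacency@neighbors[[i]]] <- 1L
  A
}

# Core cluster former on a plain t matrix (channels x time).
# Returns a list of clusters: members (2-col matrix ch, time), sumT, sign.
# Suprathreshold samples are split by sign; with minNeighbors > 0 a sample
# is retained only if at least that many of its spatial neighbors are
# suprathreshold with the same sign at the same time bin; connected
# components run over spatial adjacency (same bin) plus temporal adjacency
# (same channel, consecutive bins), same sign only. Scan order (channel
# fastest, then time) fixes the first-seen cluster ordering.
.formClustersCore <- function(tmat, nbList, A, tcrit, minNeighbors) {
  nCh <- nrow(tmat); nT <- ncol(tmat)
  s <- matrix(0L, nCh, nT)
  s[tmat > tcrit] <- 1L
  s[tmat < -tcrit] <- -1L
  if (!any(s != 0L)) return(list())
  if (minNeighbors > 0) {
    for (sg in c(1L, -1L)) {
      M <- s == sg
      if (!any(M)) next
      cnt <- A %*% M
      s[M & (cnt < minNeighbors)] <- 0L
    }
    if (!any(s != 0L)) return(list())
  }
  visited <- matrix(FALSE, nCh, nT)
  clusters <- list()
  cells <- which(s != 0L)             # linear indices, channel fastest
  for (start in cells) {
    if (visited[start]) next
    sg <- s[start]
    stack <- start
    visited[start] <- TRUE
    members <- integer(0)
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      members <- c(members, cur)
      ch <- ((cur - 1L) %% nCh) + 1L
      tb <- ((cur - 1L) %/% nCh) + 1L
      base <- (tb - 1L) * nCh
      nb <- nbList[[ch]] + base                       # spatial, same bin
      if (tb > 1L) nb <- c(nb, cur - nCh)             # temporal
      if (tb < nT) nb <- c(nb, cur + nCh)
      nb <- nb[s[nb] == sg & !visited[nb]]
      if (length(nb)) {
        visited[nb] <- TRUE
        stack <- c(stack, nb)
      }
    }
    clusters[[length(clusters) + 1L]] <- list(
      members = cbind(channel = ((members - 1L) %% nCh) + 1L,
                      time = ((members - 1L) %/% nCh) + 1L),
      linear = members,
      sumT = sum(tmat[members]),
      sign = as.integer(sg))
  }
  clusters
}

#' Form spatio-temporal clusters from a t map
#'
#' Thresholds the t map at the two-tailed first-level criterion
#' (`|t| > t_crit(df, thresholdP)`), splits suprathreshold samples by sign,
#' optionally prunes samples with fewer than `minNeighbors` same-sign
#' suprathreshold spatial neighbors at the same time bin (the
#' retained-sample convention), and groups the survivors into connected
#' components under spatial adjacency (same bin) plus temporal adjacency
#' (same channel, consecutive bins). Each cluster is summarized by the sum
#' of its t values.
#'
#' @param tmap a [SpatioTemporalTMap-class] or a plain channels x time
#'   matrix (then `df` must be given).
#' @param adjacency a [SensorAdjacency-class] covering all channels.
#' @param thresholdP two-tailed first-level p threshold (default 0.05).
#' @param minNeighbors minimal number of qualifying spatial neighbors
#'   (default 4; 0 disables pruning — appropriate for sparse generic
#'   graphs such as cortical meshes).
#' @param df degrees of freedom when `tmap` is a plain matrix.
#' @return list of clusters, each with `members` (channel/time index
#'   matrix), `channels` (labels), `sumT` and `sign`.
#' @export
formClusters <- function(tmap, adjacency, thresholdP = 0.05,
                         minNeighbors = 4, df = NULL) {
  if (is(tmap, "SpatioTemporalTMap")) {
    df <- tmap@df
    tmat <- tmap@t
  } else tmat <- tmap
  if (is.null(df)) stop("df required for a plain t matrix")
  if (nrow(tmat) != length(adjacency@labels))
    stop("adjacency must cover every channel of the t map")
  tcrit <- stats::qt(1 - thresholdP / 2, df)
  cl <- .formClustersCore(tmat, adjacency@neighbors, .adjMatrix(adjacency),
                          tcrit, minNeighbors)
  lapply(cl, function(x) {
    x$channels <- adjacency@labels[sort(unique(x$members[, "channel"]))]
    x$linear <- NULL
    x
  })
}

#' Spatio-temporal cluster permutation test
#'
#' Paired two-condition cluster test: computes the observed per-sample
#' paired t map and its clusters, then permutes the condition labels
#' (flipping a random subset of subjects) `nPermutations` times, recording
#' the maximal positive and minimal negative cluster sum at each
#' permutation (0 when a tail has no cluster). Each observed cluster gets a
#' Monte-Carlo p equal to the plain proportion of permutation extremes at
#' least as extreme as its sum (no +1 correction by default, matching the
#' proportion arithmetic `k/N`; set `plusOne = TRUE` for the
#' (k+1)/(N+1) variant), plus a Cohen's d (mean over member samples of the
#' per-sample paired d).
#'
#' The per-tail Monte-Carlo p values are reported raw; the `significant`
#' flag tests each tail at `alpha/2` (`tailCorrection = "alpha"`, default)
#' so that the overall two-tailed family-wise error stays at `alpha`.
#' `tailCorrection = "none"` flags each tail at `alpha`.
#'
#' @param a,b subject x channel x time arrays (paired design).
#' @param adjacency a [SensorAdjacency-class].
#' @param nPermutations number of label permutations (default 10000).
#' @param seed RNG seed for the permutation draws.
#' @param thresholdP first-level two-tailed threshold (default 0.05).
#' @param minNeighbors spatial-neighbor pruning (default 4).
#' @param alpha nominal two-tailed level for the significance flag.
#' @param tailCorrection `"alpha"` or `"none"` (see above).
#' @param plusOne use the (k+1)/(N+1) Monte-Carlo p variant.
#' @param chunkSize permutations per vectorized block.
#' @return a [ClusterTestResult-class] object.
#' @examples
#' adj <- sensorAdjacency(sensorLayout(8), k = 3)
#' a <- array(rnorm(6 * 8 * 10), c(6, 8, 10))
#' b <- array(rnorm(6 * 8 * 10), c(6, 8, 10))
#' res <- clusterPermutationTest(a, b, adj, nPermutations = 200, seed = 1,
#'                               minNeighbors = 0)
#' @export
clusterPermutationTest <- function(a, b, adjacency, nPermutations = 10000,
                                   seed = 1, thresholdP = 0.05,
                                   minNeighbors = 4, alpha = 0.05,
                                   tailCorrection = c("alpha", "none"),
                                   plusOne = FALSE, chunkSize = 512) {
  tailCorrection <- match.arg(tailCorrection)
  stopifnot(identical(dim(a), dim(b)), length(dim(a)) == 3)
  n <- dim(a)[1]
  if (n < 2) stop("need at least 2 subjects")
  if (nPermutations < 100) stop("nPermutations must be >= 100")
  nCh <- dim(a)[2]; nT <- dim(a)[3]
  if (nCh != length(adjacency@labels))
    stop("adjacency must cover every channel")
  D <- matrix(a - b, nrow = n)
  ss <- colSums(D^2)
  tcrit <- stats::qt(1 - thresholdP / 2, n - 1)
  nbList <- adjacency@neighbors
  A <- .adjMatrix(adjacency)

  obsT <- .tFromDiff(colMeans(D), ss, n)$t
  obsMat <- matrix(obsT, nCh, nT)
  obsClusters <- .formClustersCore(obsMat, nbList, A, tcrit, minNeighbors)

  maxDist <- numeric(nPermutations)
  minDist <- numeric(nPermutations)
  withSeed(seed, {
    done <- 0L
    while (done < nPermutations) {
      nb <- min(chunkSize, nPermutations - done)
      S <- matrix(sample(c(-1, 1), nb * n, replace = TRUE), nb, n)
      M <- (S %*% D) / n
      V <- sweep(-n * M^2, 2, ss, "+") / (n - 1)
      TT <- ifelse(V > 0, M / sqrt(V / n), 0)
      for (r in seq_len(nb)) {
        cl <- .formClustersCore(matrix(TT[r, ], nCh, nT), nbList, A,
                                tcrit, minNeighbors)
        sums <- vapply(cl, function(x) x$sumT, numeric(1))
        maxDist[done + r] <- if (any(sums > 0)) max(sums) else 0
        minDist[done + r] <- if (any(sums < 0)) min(sums) else 0
      }
      done <- done + nb
    }
  })

  denom <- nPermutations + as.integer(plusOne)
  extra <- as.integer(plusOne)
  mD <- colMeans(D); sD <- apply(D, 2, stats::sd)
  clusters <- lapply(obsClusters, function(x) {
    p <- if (x$sign > 0) (sum(maxDist >= x$sumT) + extra) / denom
         else (sum(minDist <= x$sumT) + extra) / denom
    dVals <- ifelse(sD[x$linear] > 0, mD[x$linear] / sD[x$linear], 0)
    thr <- if (tailCorrection == "alpha") alpha / 2 else alpha
    list(members = x$members,
         channels = adjacency@labels[sort(unique(x$members[, "channel"]))],
         sumT = x$sumT, sign = x$sign, p = p,
         significant = p < thr, cohenD = mean(dVals))
  })
  ord <- order(vapply(clusters, function(x) -abs(x$sumT), numeric(1)))
  clusters <- clusters[ord]
  tmap <- new("SpatioTemporalTMap", t = obsMat, df = n - 1,
              firstLevelAlpha = thresholdP)
  new("ClusterTestResult", clusters = clusters,
      maxDistribution = maxDist, minDistribution = minDist,
      nPermutations = as.integer(nPermutations), tmap = tmap,
      alpha = alpha,
      params = list(thresholdP = thresholdP, minNeighbors = minNeighbors,
                    seed = seed, tailCorrection = tailCorrection,
                    plusOne = plusOne))
}
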