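# Shared fixtures, all generated in code.

# Small, fast session configuration for sensor-level tests.
smallConfig <- function(seed, ...) {
  args <- list(...)
  base <- list(seed = seed, sfreq = 250, nChannels = 10,
               nTrialsPerCondition = 4)
  base[names(args)] <- args
  do.call(simulationConfig, base)
}

# Synthetic trace with Gaussian bumps of amplitude `amp` and width `sdMs`
# planted at `centers` (s).
bumpTrace <- function(duration, sfreq, centers, amp = 1, sdMs = 12) {
  n <- round(duration * sfreq)
  x <- numeric(n)
  half <- ceiling(4 * sdMs / 1000 * sfreq)
  rel <- seq(-half, half)
  shape <- amp * exp(-0.5 * (rel / sfreq * 1000 / sdMs)^2)
  for (tc in centers) {
    idx <- round(tc * sfreq) + 1L + rel
    keep <- idx >= 1 & idx <= n
    x[idx[keep]] <- x[idx[keep]] + shape[keep]
  }
  x
}

# Linear chain adjacency CH1 - CH2 - ... - CHn.
chainAdjacency <- function(n) {
  labs <- paste0("CH", seq_len(n))
  nb <- lapply(seq_len(n), function(i)
    labs[c(i - 1, i + 1)[c(i - 1, i + 1) >= 1 & c(i - 1, i + 1) <= n]])
  adjacencyFromList(stats::setNames(nb, labs))
}

# Independent brute-force cluster oracle built on igraph: connect
# same-sign suprathreshold samples through spatial (same bin) and temporal
# (same channel, consecutive bins) adjacency and take connected components.
bruteforceClusters <- function(tmat, adjacency, tcrit, minNeighbors = 0) {
  nCh <- nrow(tmat); nT <- ncol(tmat)
  sgn <- matrix(0L, nCh, nT)
  sgn[tmat > tcrit] <- 1L
  sgn[tmat < -tcrit] <- -1L
  nb <- adjacency@neighbors
  if (minNeighbors > 0) {
    keep <- matrix(FALSE, nCh, nT)
    for (ch in seq_len(nCh)) for (tb in seq_len(nT)) {
      if (sgn[ch, tb] == 0L) next
      cnt <- sum(sgn[nb[[ch]], tb] == sgn[ch, tb])
      keep[ch, tb] <- cnt >= minNeighbors
    }
    sgn[!keep] <- 0L
  }
  cells <- which(sgn != 0L)
  if (!length(cells)) return(list())
  id <- match(cells, cells)
  edges <- integer(0)
  for (k in seq_along(cells)) {
    cell <- cells[k]
    ch <- ((cell - 1L) %% nCh) + 1L
    tb <- ((cell - 1L) %/% nCh) + 1L
    cand <- c((tb - 1L) * nCh + nb[[ch]],
              if (tb > 1) cell - nCh, if (tb < nT) cell + nCh)
    for (cc in cand) {
      j <- match(cc, cells)
      if (!is.na(j) && sgn[cc] == sgn[cell]) edges <- c(edges, k, j)
    }
  }
  g <- igraph::make_empty_graph(n = length(cells), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  lapply(seq_len(max(comp)), function(m) {
    mem <- cells[comp == m]
    list(members = sort(mem), sumT = sum(tmat[mem]),
         sign = unique(sgn[mem]))
  })
}

# Canonical cluster representation for comparison: sorted member indices +
# rounded sum, ordered by first member.
canonicalClusters <- function(cl, nCh) {
  reps <- lapply(cl, function(x) {
    lin <- if (!is.null(x$members) && is.matrix(x$members))
      sort((x$members[, "time"] - 1L) * nCh + x$members[, "channel"])
    else sort(x$members)
    list(lin = as.integer(lin), sumT = round(x$sumT, 10))
  })
  reps[order(vapply(reps, function(r) r$lin[1], numeric(1)))]
}

# Subject-level difference arrays with an optional planted effect.
nullArrays <- function(seed, nSub, nCh, nT) {
  set.seed(seed)
  list(a = array(stats::rnorm(nSub * nCh * nT), c(nSub, nCh, nT)),
       b = array(stats::rnorm(nSub * nCh * nT), c(nSub, nCh, nT)))
}
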