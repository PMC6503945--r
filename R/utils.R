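# Internal helpers.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from one master seed (kept < 2^31).
childSeeds <- function(seed, n) {
  (as.numeric(seed) * 7919 + 104729 * seq_len(n)) %% 2147483629
}

# Sliding-window maximum/minimum, window w samples, aligned so that
# result[i] covers x[i .. i+w-1]; length(result) = length(x) - w + 1.
# Prefix/suffix block decomposition, O(n).
runningMax <- function(x, w) {
  n <- length(x)
  if (w > n) stop("window longer than the trace")
  nb <- ceiling(n / w)
  pad <- nb * w - n
  xp <- c(x, rep(-Inf, pad))
  m <- matrix(xp, nrow = w)
  pre <- apply(m, 2, cummax)                      # block prefix maxima
  suf <- apply(m[w:1, , drop = FALSE], 2, cummax)[w:1, , drop = FALSE]
  pre <- as.vector(pre); suf <- as.vector(suf)
  i <- seq_len(n - w + 1)
  pmax(suf[i], pre[i + w - 1])
}

runningMin <- function(x, w) -runningMax(-x, w)

# Merge overlapping/touching intervals given as a 2-column matrix (start, end).
mergeIntervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0) return(matrix(numeric(0), ncol = 2))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (k in seq_len(nrow(iv))[-1]) {
    last <- nrow(out)
    if (iv[k, 1] <= out[last, 2]) {
      out[last, 2] <- max(out[last, 2], iv[k, 2])
    } else out <- rbind(out, iv[k, ])
  }
  out
}

# TRUE for each x inside any interval (inclusive).
inAnyInterval <- function(x, iv) {
  if (nrow(iv) == 0) return(rep(FALSE, length(x)))
  hit <- rep(FALSE, length(x))
  for (k in seq_len(nrow(iv))) hit <- hit | (x >= iv[k, 1] & x <= iv[k, 2])
  hit
}

# z-score that errors on degenerate input.
zscore <- function(x, what = "variable") {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("cannot z-score '", what, "': zero variance")
  (x - mean(x)) / s
}

# Stable MD5 of an R object via its canonical JSON serialization.
configHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}
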