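#' Zero-phase Butterworth filtering
#'
#' Forward-backward (zero-phase) Butterworth filtering, the phase handling
#' used throughout the pipeline: a causal filter would shift the narrow HER
#' latency windows. The trace is reflection-padded at both ends before
#' `signal::filtfilt` to suppress edge transients.
#'
#' @param x numeric vector (one trace) or matrix (channels x samples,
#'   filtered row-wise).
#' @param sfreq sampling frequency, Hz.
#' @param low high-pass corner, Hz, or `NULL` for low-pass only.
#' @param high low-pass corner, Hz, or `NULL` for high-pass only.
#' @param order filter order (applied once per direction; default 4).
#' @return filtered data, same shape as `x`.
#' @examples
#' x <- sin(2 * pi * 2 * seq(0, 2, by = 1e-3)) + rnorm(2001, sd = .1)
#' xf <- butterFilter(x, 1000, low = NULL, high = 10)
#' @export
butterFilter <- function(x, sfreq, low = NULL, high = NULL, order = 4) {
  if (is.matrix(x)) {
    out <- x
    for (i in seq_len(nrow(x)))
      out[i, ] <- butterFilter(x[i, ], sfreq, low, high, order)
    return(out)
  }
  if (is.null(low) && is.null(high)) return(x)
  nyq <- sfreq / 2
  if (!is.null(high) && high >= nyq)
    stop("low-pass corner must be below the Nyquist frequency")
  bf <- if (!is.null(low) && !is.null(high)) {
    signal::butter(order, c(low, high) / nyq, type = "pass")
  } else if (!is.null(high)) {
    signal::butter(order, high / nyq, type = "low")
  } else {
    signal::butter(order, low / nyq, type = "high")
  }
  n <- length(x)
  pad <- min(n - 1, max(3 * order * 10, round(sfreq)))
  xp <- c(2 * x[1] - x[seq(pad + 1, 2)], x, 2 * x[n] - x[seq(n - 1, n - pad)])
  y <- signal::filtfilt(bf, xp)
  y[(pad + 1):(pad + n)]
}
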