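# Trial-level GLMs, group tests, Fisher-z correlation tests and Bayes
# factors with Jeffreys-style evidence labels.
#
# Bayes factor orientation throughout: BF > 1 supports the null.

.checkRank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  q
}

.olsBeta <- function(X, y) {
  q <- .checkRank(X)
  b <- qr.coef(q, y)
  b[colnames(X)]
}

#' Per-subject GLM on trial-wise HER cluster amplitudes
#'
#' Fits an ordinary least-squares model predicting the per-trial HER
#' cluster amplitude from 8 regressors: the condition (coded +1 for Self,
#' -1 for Other), the three rating scales, the interaction of the condition
#' code with each (z-scored) rating, and the trial number. The response,
#' the ratings and the trial number are z-scored within subject before
#' fitting; the interaction terms are the product of the +/-1 code with the
#' z-scored rating (not re-z-scored).
#'
#' @param data data.frame with one row per trial: `amplitude`, `condition`
#'   (`"Self"`/`"Other"`), `perspective`, `valence`, `arousal`, `trial`.
#' @return a [GLMResult-class] with the 8 betas.
#' @export
fitHERGlm <- function(data) {
  need <- c("amplitude", "condition", "perspective", "valence", "arousal",
            "trial")
  stopifnot(all(need %in% names(data)))
  data <- data[stats::complete.cases(data[need]), , drop = FALSE]
  if (nrow(data) < 10) stop("need at least 10 trials with complete ratings")
  y <- zscore(data$amplitude, "amplitude")
  cond <- ifelse(data$condition == "Self", 1, -1)
  zP <- zscore(data$perspective, "perspective")
  zV <- zscore(data$valence, "valence")
  zA <- zscore(data$arousal, "arousal")
  zTr <- zscore(data$trial, "trial number")
  X <- cbind(intercept = 1, condition = cond,
             perspective = zP, valence = zV, arousal = zA,
             condition_x_perspective = cond * zP,
             condition_x_valence = cond * zV,
             condition_x_arousal = cond * zA,
             trial_number = zTr)
  b <- .olsBeta(X, y)[-1]
  new("GLMResult", beta = b, regressors = names(b),
      zScored = c("amplitude", "perspective", "valence", "arousal",
                  "trial_number"),
      n = nrow(data))
}

#' Per-subject GLM on trial-wise heartbeat counts
#'
#' Predicts the (z-scored) number of eligible heartbeats per trial from 4
#' regressors: the +/-1 condition code and the three z-scored rating
#' scales.
#'
#' @param data data.frame with `nBeats`, `condition`, `perspective`,
#'   `valence`, `arousal` per trial.
#' @return a [GLMResult-class] with the 4 betas.
#' @export
fitHeartbeatCountGlm <- function(data) {
  need <- c("nBeats", "condition", "perspective", "valence", "arousal")
  stopifnot(all(need %in% names(data)))
  data <- data[stats::complete.cases(data[need]), , drop = FALSE]
  if (nrow(data) < 10) stop("need at least 10 trials with complete ratings")
  y <- zscore(data$nBeats, "heartbeat count")
  cond <- ifelse(data$condition == "Self", 1, -1)
  X <- cbind(intercept = 1, condition = cond,
             perspective = zscore(data$perspective, "perspective"),
             valence = zscore(data$valence, "valence"),
             arousal = zscore(data$arousal, "arousal"))
  b <- .olsBeta(X, y)[-1]
  new("GLMResult", beta = b, regressors = names(b),
      zScored = c("nBeats", "perspective", "valence", "arousal"),
      n = nrow(data))
}

#' Group-level test of per-subject betas against zero
#'
#' One-sample t test per regressor over subjects. Zero-variance nonzero
#' betas make t undefined: the regressor is flagged degenerate with a
#' warning (all-zero betas give t = 0, p = 1).
#'
#' @param betas matrix subjects x regressors (colnames = regressor names)
#'   or list of [GLMResult-class] objects.
#' @return data.frame with `regressor`, `meanBeta`, `t`, `df`, `p`,
#'   `degenerate`.
#' @export
groupBetaTest <- function(betas) {
  if (is.list(betas) && !is.data.frame(betas) && !is.matrix(betas))
    betas <- do.call(rbind, lapply(betas, function(g) g@beta))
  stopifnot(is.matrix(betas), nrow(betas) >= 2)
  n <- nrow(betas)
  out <- lapply(seq_len(ncol(betas)), function(j) {
    x <- betas[, j]
    m <- mean(x); s <- stats::sd(x)
    if (s == 0) {
      if (m == 0) data.frame(meanBeta = 0, t = 0, df = n - 1, p = 1,
                             degenerate = FALSE)
      else {
        warning("zero-variance betas with nonzero mean for regressor ",
                colnames(betas)[j], "; t undefined")
        data.frame(meanBeta = m, t = NA_real_, df = n - 1, p = NA_real_,
                   degenerate = TRUE)
      }
    } else {
      tv <- m / (s / sqrt(n))
      data.frame(meanBeta = m, t = tv, df = n - 1,
                 p = 2 * stats::pt(-abs(tv), n - 1), degenerate = FALSE)
    }
  })
  cbind(regressor = colnames(betas), do.call(rbind, out))
}

#' Group test of Fisher-z transformed correlations
#'
#' Transforms per-subject Pearson correlations with `atanh` and tests the
#' transformed values against zero with a one-sample t test; also reports
#' the mean correlation and its square (shared variance).
#'
#' @param r per-subject correlation coefficients, all `|r| < 1`.
#' @return a [GroupCorrelationResult-class] object.
#' @examples
#' fisherZGroupTest(c(0.2, 0.1, 0.25, 0.18))
#' @export
fisherZGroupTest <- function(r) {
  if (any(abs(r) >= 1)) stop("Fisher transform diverges at |r| = 1")
  if (length(r) < 2) stop("need at least 2 subjects")
  z <- atanh(r)
  n <- length(z)
  s <- stats::sd(z)
  tv <- if (s == 0 && mean(z) == 0) 0
        else mean(z) / (s / sqrt(n))
  p <- if (is.finite(tv)) 2 * stats::pt(-abs(tv), n - 1) else NA_real_
  new("GroupCorrelationResult", r = r, z = z, meanR = mean(r),
      rSquared = mean(r)^2, t = tv, p = p, df = n - 1)
}

#' BIC Bayes factor for a paired (one-sample) design
#'
#' Compares the maximum-likelihood Gaussian model of the per-subject
#' differences with mean fixed at zero (null) against the free-mean model
#' (effect), penalized by the Bayesian information criterion:
#' \deqn{BF_{01} = \exp((BIC_{effect} - BIC_{null})/2)}
#' which equals \eqn{\sqrt{n}\,((n-1)/(n-1+t^2))^{n/2}}. BF01 is strictly
#' decreasing in |t| at fixed n and exceeds 1 when the sample mean is 0.
#'
#' @param differences per-subject paired differences (n >= 3, nonzero
#'   variance).
#' @return a [BayesFactorResult-class] (method `"bic_paired"`).
#' @export
bfBICPaired <- function(differences) {
  n <- length(differences)
  if (n < 3) stop("need at least 3 subjects")
  m <- mean(differences)
  v1 <- mean((differences - m)^2)   # ML variance, effect model
  v0 <- mean(differences^2)         # ML variance, null model
  if (v1 <= 0) stop("zero-variance differences")
  ll <- function(v) -n / 2 * (log(2 * pi * v) + 1)
  bic0 <- -2 * ll(v0) + log(n)
  bic1 <- -2 * ll(v1) + 2 * log(n)
  bf <- exp((bic1 - bic0) / 2)
  new("BayesFactorResult", bf = bf, method = "bic_paired",
      label = bfLabel(bf))
}

# JZS integrals (Cauchy prior on the standardized effect via the
# normal-times-inverse-gamma mixture representation).
.jzsT <- function(t, N, nu, rscale = sqrt(2) / 2) {
  dens0 <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  f <- function(g) {
    a <- 1 + N * g * rscale^2
    a^(-1 / 2) * (1 + t^2 / (a * nu))^(-(nu + 1) / 2) *
      (2 * pi)^(-1 / 2) * g^(-3 / 2) * exp(-1 / (2 * g))
  }
  num <- stats::integrate(f, 0, Inf, rel.tol = 1e-9)$value
  num / dens0                                     # BF10
}

.jzsCorrelation <- function(r, n) {
  # marginal over the Zellner-Siow g-prior for a single regressor
  f <- function(g) {
    (1 + g)^((n - 2) / 2) * (1 + (1 - r^2) * g)^(-(n - 1) / 2) *
      g^(-3 / 2) * exp(-n / (2 * g))
  }
  int <- stats::integrate(f, 0, Inf, rel.tol = 1e-9)$value
  sqrt(n / 2) / gamma(1 / 2) * int                 # BF10
}

#' JZS Bayes factors (correlation, one- and two-sample t)
#'
#' Default-prior (Jeffreys-Zellner-Siow) Bayes factors computed by
#' numerical integration over the Cauchy-scale mixing parameter, reported
#' in the BF > 1 supports-the-null orientation. For t tests the Cauchy
#' prior scale on the standardized effect is `sqrt(2)/2`.
#'
#' @param r Pearson correlation (method `"correlation"`).
#' @param n sample size (correlation / one-sample).
#' @param t t statistic (t-test methods).
#' @param n1,n2 group sizes (two-sample).
#' @param method `"correlation"`, `"one_sample"` or `"two_sample"`.
#' @return a [BayesFactorResult-class] object.
#' @examples
#' bfJZS(r = 0.18, n = 19, method = "correlation")
#' @export
bfJZS <- function(r = NULL, n = NULL, t = NULL, n1 = NULL, n2 = NULL,
                  method = c("correlation", "one_sample", "two_sample")) {
  method <- match.arg(method)
  bf10 <- switch(method,
    correlation = {
      stopifnot(!is.null(r), !is.null(n), abs(r) < 1, n > 3)
      .jzsCorrelation(r, n)
    },
    one_sample = {
      stopifnot(!is.null(t), !is.null(n), n > 1)
      .jzsT(t, N = n, nu = n - 1)
    },
    two_sample = {
      stopifnot(!is.null(t), !is.null(n1), !is.null(n2))
      .jzsT(t, N = n1 * n2 / (n1 + n2), nu = n1 + n2 - 2)
    })
  bf01 <- 1 / bf10
  new("BayesFactorResult", bf = bf01,
      method = paste0("jzs_", method), label = bfLabel(bf01))
}

#' Jeffreys-style evidence label for a Bayes factor
#'
#' Categorizes `max(bf, 1/bf)`: below 3 anecdotal, 3-10 substantial, 10-30
#' strong, 30-100 very strong, above 100 decisive; the direction is H0 for
#' BF > 1 and H1 for BF < 1 (BF > 1 supports the null throughout).
#'
#' @param bf Bayes factor, > 0.
#' @return character label, e.g. `"substantial evidence for H0"`.
#' @examples
#' bfLabel(4.12)
#' bfLabel(0.078)
#' @export
bfLabel <- function(bf) {
  stopifnot(is.finite(bf), bf > 0)
  if (bf == 1) return("no evidence either way")
  m <- max(bf, 1 / bf)
  cat_ <- if (m < 3) "anecdotal" else if (m < 10) "substantial"
          else if (m < 30) "strong" else if (m < 100) "very strong"
          else "decisive"
  sprintf("%s evidence for %s", cat_, if (bf > 1) "H0" else "H1")
}
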