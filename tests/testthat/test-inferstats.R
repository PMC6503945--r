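makeTrialFrame <- function(n = 24, seed = 1) {
  set.seed(seed)
  data.frame(amplitude = rnorm(n),
             condition = rep(c("Self", "Other"), n / 2),
             perspective = sample(1:5, n, TRUE),
             valence = sample(-2:2, n, TRUE),
             arousal = sample(1:5, n, TRUE),
             trial = seq_len(n))
}

test_that("HER GLM betas match the closed-form least-squares solution", {
  df <- makeTrialFrame(seed = 80)
  fit <- fitHERGlm(df)
  z <- function(x) (x - mean(x)) / sd(x)
  cond <- ifelse(df$condition == "Self", 1, -1)
  X <- cbind(1, cond, z(df$perspective), z(df$valence), z(df$arousal),
             cond * z(df$perspective), cond * z(df$valence),
             cond * z(df$arousal), z(df$trial))
  ref <- solve(crossprod(X), crossprod(X, z(df$amplitude)))[-1]
  expect_equal(unname(fit@beta), as.vector(ref), tolerance = 1e-10)
  expect_length(fit@beta, 8)
})

test_that("a response equal to the condition code loads only on condition", {
  df <- makeTrialFrame(seed = 81)
  df$amplitude <- ifelse(df$condition == "Self", 1, -1)
  fit <- fitHERGlm(df)
  expect_equal(unname(fit@beta["condition"]), 1, tolerance = 0.05)
  expect_lt(max(abs(fit@beta[c("perspective", "valence", "arousal")])), 0.2)
})

test_that("collinear designs fail with the offending column named", {
  df <- makeTrialFrame(seed = 82)
  df$valence <- df$perspective - 3   # perfectly collinear
  expect_error(fitHERGlm(df), "collinear")
})

test_that("heartbeat-count GLM recovers a pure arousal dependence", {
  df <- makeTrialFrame(seed = 83)
  df$nBeats <- df$arousal
  fit <- fitHeartbeatCountGlm(df)
  expect_equal(unname(fit@beta["arousal"]), 1, tolerance = 1e-10)
  expect_lt(max(abs(fit@beta[c("condition", "perspective", "valence")])),
            1e-10)
  df$nBeats <- 6
  expect_error(fitHeartbeatCountGlm(df), "zero variance")
})

test_that("count GLM betas are null when counts ignore the ratings", {
  # group-level check over simulated subjects
  res <- vapply(1:30, function(s) {
    df <- makeTrialFrame(n = 36, seed = 500 + s)
    df$nBeats <- rpois(36, 6)
    fitHeartbeatCountGlm(df)@beta
  }, numeric(4))
  gt <- groupBetaTest(t(res))
  expect_true(all(gt$p > 0.001))
  expect_lt(max(abs(gt$meanBeta)), 0.15)
})

test_that("group beta tests handle degenerate inputs as specified", {
  expect_equal(groupBetaTest(matrix(0, 5, 2,
                                    dimnames = list(NULL, c("x", "y"))))$t,
               c(0, 0))
  expect_equal(groupBetaTest(matrix(0, 5, 1,
                                    dimnames = list(NULL, "x")))$p, 1)
  expect_warning(
    out <- groupBetaTest(matrix(1, 3, 1, dimnames = list(NULL, "x"))),
    "zero-variance")
  expect_true(out$degenerate)
  set.seed(84)
  m <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  gt <- groupBetaTest(m)
  for (j in 1:3) {
    ref <- t.test(m[, j])
    expect_equal(gt$t[j], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(gt$p[j], ref$p.value, tolerance = 1e-12)
  }
})

test_that("Fisher-z group tests report r, r squared and the t statistic", {
  z0 <- fisherZGroupTest(rep(0, 6))
  expect_equal(z0@t, 0)
  r <- c(0.18, 0.18, 0.18, 0.18)
  res <- fisherZGroupTest(r)
  expect_equal(res@meanR, 0.18)
  expect_equal(res@rSquared, 0.0324)        # 3.2% shared variance
  expect_error(fisherZGroupTest(c(0.5, 1)), "diverges")
  set.seed(85)
  rr <- runif(8, -0.5, 0.5)
  ref <- t.test(atanh(rr))
  expect_equal(fisherZGroupTest(rr)@t, unname(ref$statistic),
               tolerance = 1e-12)
})

test_that("the BIC Bayes factor favors the null at zero mean and falls in |t|", {
  bf0 <- bfBICPaired(c(-2, -1, 0, 1, 2))
  expect_gt(bayesFactor(bf0), 1)
  # numeric sweep: fixed residuals, growing mean shift
  resid <- scale(rnorm(23), center = TRUE, scale = FALSE)[, 1]
  bfs <- vapply(seq(0, 3, by = 0.25),
                function(m) bayesFactor(bfBICPaired(resid + m)), numeric(1))
  expect_true(all(diff(bfs) < 0))
  expect_error(bfBICPaired(rep(1, 5)), "zero-variance")
  expect_error(bfBICPaired(c(1, 2)), "3 subjects")
})

test_that("JZS Bayes factors have the documented direction and monotonicity", {
  bfNull <- bfJZS(r = 0, n = 23, method = "correlation")
  expect_gt(bayesFactor(bfNull), 1)
  rGrid <- seq(0, 0.95, by = 0.05)
  bfs <- vapply(rGrid, function(r)
    bayesFactor(bfJZS(r = r, n = 23, method = "correlation")), numeric(1))
  expect_true(all(diff(bfs) < 0))
  expect_lt(bayesFactor(bfJZS(r = 0.99, n = 23, method = "correlation")),
            0.001)
  # two-sample: monotone decreasing in |t|, symmetric in sign
  tGrid <- seq(0, 5, by = 0.5)
  bft <- vapply(tGrid, function(tv)
    bayesFactor(bfJZS(t = tv, n1 = 23, n2 = 23, method = "two_sample")),
    numeric(1))
  expect_true(all(diff(bft) < 0))
  expect_equal(bayesFactor(bfJZS(t = -2, n1 = 23, n2 = 23,
                                 method = "two_sample")),
               bayesFactor(bfJZS(t = 2, n1 = 23, n2 = 23,
                                 method = "two_sample")), tolerance = 1e-9)
  expect_gt(bayesFactor(bfJZS(t = 0.1, n = 20, method = "one_sample")), 1)
})

test_that("evidence labels reproduce every printed Bayes factor reading", {
  pairs <- list(
    list(1.45, "anecdotal evidence for H0"),
    list(4.12, "substantial evidence for H0"),
    list(3.96, "substantial evidence for H0"),
    list(2.80, "anecdotal evidence for H0"),
    list(3.36, "substantial evidence for H0"),
    list(0.0018, "decisive evidence for H1"),
    list(0.0067, "decisive evidence for H1"),
    list(0.078, "strong evidence for H1"),
    list(0.60, "anecdotal evidence for H1"),
    list(2.02, "anecdotal evidence for H0"),
    list(2.88, "anecdotal evidence for H0"),
    list(0.82, "anecdotal evidence for H1"),
    list(2.26, "anecdotal evidence for H0"),
    list(3.92, "substantial evidence for H0"),
    list(0.75, "anecdotal evidence for H1"),
    list(2.72, "anecdotal evidence for H0"),
    list(2.61, "anecdotal evidence for H0"),
    list(2.10, "anecdotal evidence for H0"),
    list(1.52, "anecdotal evidence for H0"),
    list(0.53, "anecdotal evidence for H1"),
    list(0.04, "strong evidence for H1"))
  for (p in pairs) expect_identical(bfLabel(p[[1]]), p[[2]])
  expect_error(bfLabel(-1))
})
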