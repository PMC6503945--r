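test_that("identical relative phase gives PPC of one", {
  sim <- simulateECG(simulationConfig(seed = 40), duration = 30)
  ecg <- sim$ecg$II
  rt <- rTimes(sim$groundTruth)
  expect_equal(ppcScore(2.5 * ecg, ecg, rt, 1000), 1, tolerance = 1e-9)
})

test_that("two epochs in antiphase give PPC of minus one", {
  sf <- 250
  tt <- seq(0, 3.999, by = 1 / sf)
  ecgTrace <- sin(2 * pi * 5 * tt)
  comp <- ecgTrace
  # sign-flip the component inside the second epoch only: the relative
  # phase shifts by pi at every bin, a single pair, so PPC = cos(pi)
  comp[351:450] <- -comp[351:450]
  ppc <- ppcScore(comp, ecgTrace, c(0.8, 1.6), sf, band = c(4, 6))
  expect_equal(ppc, -1, tolerance = 1e-6)
})

test_that("independent phases give PPC near zero", {
  set.seed(41)
  n <- 300 * 250
  comp <- rnorm(n)
  ecg <- rnorm(n)
  rt <- seq(1, 299, by = 1.5)
  ppc <- ppcScore(comp, ecg, rt, 250)
  expect_lt(abs(ppc), 0.05)
})

test_that("PPC is invariant to amplitude scaling of the component", {
  set.seed(42)
  comp <- rnorm(250 * 30); ecg <- rnorm(250 * 30)
  rt <- seq(1, 28, by = 1)
  expect_equal(ppcScore(comp, ecg, rt, 250),
               ppcScore(100 * comp, ecg, rt, 250), tolerance = 1e-12)
})

test_that("PPC input validation errors are explicit", {
  expect_error(ppcScore(rnorm(1000), rnorm(1000), numeric(0), 250), "epochs")
  expect_error(ppcScore(rnorm(1000), rnorm(1000), 2, 250, band = c(0, 200)),
               "Nyquist")
})

test_that("the cardiac component selection rule finds the planted component", {
  sim <- simulateECG(simulationConfig(seed = 43), duration = 60)
  ecg <- sim$ecg$II
  rt <- rTimes(sim$groundTruth)
  set.seed(43)
  traces <- rbind(matrix(rnorm(7 * length(ecg)), 7), 0.3 * ecg + rnorm(length(ecg), sd = 0.02))
  scores <- apply(traces, 1, ppcScore, ecgTrace = ecg, rTimes = rt,
                  sfreq = 1000)
  sel <- selectCardiacComponents(scores)
  expect_identical(which(sel$selected), 8L)
})

test_that("equal scores select nothing and the cap of two holds", {
  sel <- selectCardiacComponents(rep(0.2, 6))
  expect_false(any(sel$selected))
  # three clear outliers, still at most two selected
  sel2 <- selectCardiacComponents(c(rnorm(9, 0, 0.01), 0.8, 0.85, 0.9))
  expect_lte(sum(sel2$selected), 2)
})

test_that("blink component selection follows the 3-SD rule with cap three", {
  set.seed(44)
  n <- 250 * 60
  veog <- rnorm(n)
  # enough background components that a single outlier cannot mask itself
  # by inflating the pooled SD
  traces <- rbind(matrix(rnorm(16 * n), 16), veog + rnorm(n, sd = 0.3))
  sel <- selectBlinkComponents(traces, veog)
  expect_identical(which(sel$selected), 17L)
  orth <- matrix(rnorm(6 * n), 6)
  expect_false(any(selectBlinkComponents(orth, veog)$selected))
  planted <- rbind(matrix(rnorm(6 * n), 6),
                   veog + rnorm(n, sd = .1), veog + rnorm(n, sd = .1),
                   veog + rnorm(n, sd = .1), veog + rnorm(n, sd = .1))
  expect_lte(sum(selectBlinkComponents(planted, veog)$selected), 3)
})

test_that("removing selected components subtracts their contribution", {
  set.seed(45)
  comp <- matrix(rnorm(3 * 1000), 3)
  mix <- matrix(rnorm(5 * 3), 5)
  data <- mix %*% comp
  cleaned <- removeComponents(data, mix, comp, selected = c(1, 3))
  expect_equal(cleaned, mix[, 2, drop = FALSE] %*% comp[2, , drop = FALSE],
               tolerance = 1e-12)
  expect_identical(removeComponents(data, mix, comp, integer(0)), data)
})

test_that("a clean pupil trace yields zero interpolation and z-scored epochs", {
  sf <- 250
  trials <- data.frame(trial = 1:3,
                       imagination_onset = c(2, 12, 22),
                       imagination_offset = c(9, 19, 29))
  trace <- 0.2 * sin(2 * pi * 0.1 * seq_len(32 * sf) / sf)
  pe <- preprocessPupil(trace, sf, NULL, trials)
  expect_equal(pe@interpolatedFraction, rep(0, 3))
  expect_true(all(pe@retained))
  for (i in 1:3) {
    expect_equal(mean(pe@epochs[i, ]), 0, tolerance = 1e-9)
    expect_equal(sd(pe@epochs[i, ]), 1, tolerance = 1e-9)
  }
})

test_that("a 700 ms blink inside a 2 s epoch drops the epoch", {
  sf <- 250
  trials <- data.frame(trial = 1L, imagination_onset = 2,
                       imagination_offset = 9)
  trace <- 0.1 * sin(2 * pi * 0.1 * seq_len(12 * sf) / sf)
  # blink fully inside the [2, 4] s post-onset epoch ([4, 6] absolute)
  blink <- cbind(4.5, 5.2)
  pe <- preprocessPupil(trace, sf, blink, trials)
  # (700 + 2 * 80) ms interpolated out of 2000 ms = 0.43 > 0.30
  expect_equal(pe@interpolatedFraction[1], 0.43, tolerance = 0.02)
  expect_false(pe@retained[1])
})

test_that("noisy 300 ms windows are interpolated", {
  sf <- 250
  trials <- data.frame(trial = 1L, imagination_onset = 2,
                       imagination_offset = 9)
  trace <- numeric(12 * sf)
  trace[round(4.4 * sf):round(4.5 * sf)] <- 3   # range > 1 within 300 ms
  pe <- preprocessPupil(trace, sf, NULL, trials)
  expect_gt(pe@interpolatedFraction[1], 0)
})

test_that("an epoch outside the trace is dropped with full mask", {
  sf <- 100
  trials <- data.frame(trial = 1:2, imagination_onset = c(1, 50),
                       imagination_offset = c(8, 57))
  trace <- rep(0.01, 10 * sf)
  pe <- preprocessPupil(trace, sf, NULL, trials)
  expect_true(pe@retained[1])
  expect_false(pe@retained[2])
})

test_that("low-retention subjects are flagged below mean minus 1.5 SD", {
  counts <- c(30, 31, 29, 32, 30, 8)
  flags <- flagLowRetention(counts)
  expect_identical(which(flags), 6L)
})
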