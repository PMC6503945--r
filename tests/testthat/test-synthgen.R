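test_that("renewal heartbeat count matches the expected rate", {
  counts <- vapply(1:5, function(s) {
    sim <- simulateECG(simulationConfig(seed = s, ibiSd = 25), duration = 60)
    length(rTimes(sim$groundTruth))
  }, numeric(1))
  # 60 s / 0.854 s ~ 70.3 beats; allow sampling error plus the end margin
  expect_gt(mean(counts), 67)
  expect_lt(mean(counts), 72)
})

test_that("every beat carries exactly one T peak at the configured lag", {
  sim <- simulateECG(simulationConfig(seed = 2), duration = 20)
  gt <- sim$groundTruth
  expect_equal(length(rTimes(gt)), length(tTimes(gt)))
  expect_equal(tTimes(gt) - rTimes(gt),
               rep(0.280, length(rTimes(gt))))
})

test_that("zero interbeat variability gives exactly regular beats", {
  sim <- simulateECG(simulationConfig(seed = 3, ibiSd = 0), duration = 20)
  expect_equal(diff(rTimes(sim$groundTruth)),
               rep(0.854, length(rTimes(sim$groundTruth)) - 1))
})

test_that("degenerate renewal configurations are rejected", {
  expect_error(simulationConfig(ibiSd = 900), "ibiSd")
  expect_error(simulationConfig(ibiMean = -1), "ibiMean")
  expect_error(simulationConfig(effectWindow = c(50, 100)), "effectWindow")
  expect_error(simulationConfig(imaginationRange = c(7.3, 6.7)))
  expect_error(simulateECG(simulationConfig(), duration = 2), "duration")
})

test_that("session generation is deterministic under a fixed seed", {
  cfg <- smallConfig(42)
  s1 <- simulateSession(cfg)
  s2 <- simulateSession(cfg)
  expect_identical(sensorData(s1$recording), sensorData(s2$recording))
  expect_identical(s1$trials, s2$trials)
  expect_identical(rTimes(s1$groundTruth), rTimes(s2$groundTruth))
})

test_that("trial timing respects every configured range", {
  cfg <- smallConfig(5, nTrialsPerCondition = 10)
  tr <- simulateSession(cfg, sensors = FALSE)$trials
  expect_true(all(table(tr$condition) == 10))
  fix <- tr$instruction_onset - tr$fixation_onset
  expect_true(all(fix >= 1.0 - 1e-9 & fix <= 1.3 + 1e-9))
  instr <- tr$imagination_onset - tr$instruction_onset
  expect_equal(instr, rep(2.3, nrow(tr)))
  imag <- tr$imagination_offset - tr$imagination_onset
  expect_true(all(imag >= 6.7 - 1e-9 & imag <= 7.3 + 1e-9))
  gap <- tr$fixation_onset[-1] - tr$imagination_offset[-nrow(tr)]
  expect_true(all(gap >= 4.5 + 4.5 - 1e-9 & gap <= 4.5 + 5.4 + 1e-9))
  expect_silent(validateTrialTable(tr))
  expect_true(all(tr$perspective %in% 1:5) && all(tr$arousal %in% 1:5) &&
                all(tr$valence %in% -2:2))
})

test_that("planted arousal gap is recovered across simulated subjects", {
  deltas <- vapply(1:20, function(s) {
    tr <- simulateSession(smallConfig(100 + s, nTrialsPerCondition = 36),
                          sensors = FALSE)$trials
    mean(tr$arousal[tr$condition == "Self"]) -
      mean(tr$arousal[tr$condition == "Other"])
  }, numeric(1))
  expect_gt(mean(deltas), 0.15)   # planted 3.4 vs 3.0
  expect_lt(mean(deltas), 0.65)
})

test_that("noise-free construction recovers the planted effect exactly", {
  cfg <- smallConfig(7, cardiacArtifactGain = 0, sensorNoiseSd = 0,
                     effectAmplitudeSelf = -2, effectAmplitudeOther = -0.5,
                     nTrialsPerCondition = 3)
  ses <- simulateSession(cfg)
  ev <- groundTruthEvents(ses$groundTruth)
  elig <- selectHeartbeats(ses$trials, ev)
  ep <- extractHEREpochs(ses$recording, elig, lowpass = NULL,
                         artifactMultiple = Inf)
  avg <- averageHER(ep)
  es <- ses$groundTruth@effectSensors[1]
  ci <- match(es, channelLabels(ep))
  tms <- epochTimes(ep)
  d <- avg@averages$Self[ci, ] - avg@averages$Other[ci, ]
  # the planted bump is a unit half-sine over the sample grid spanning
  # 307-326 ms; reconstruct it independently on the epoch time axis
  sf <- sfreq(ep)
  grid <- seq(round(0.307 * sf), round(0.326 * sf))
  shape <- sin(pi * (seq_along(grid) - 1) / (length(grid) - 1))
  relOffsets <- round(tms * sf / 1000)
  expected <- (-2 - (-0.5)) *
    ifelse(relOffsets %in% grid, shape[match(relOffsets, grid)], 0)
  expect_equal(unname(d), expected, tolerance = 1e-10)
})

test_that("equal planted amplitudes give a zero expected difference", {
  cfg <- smallConfig(8, cardiacArtifactGain = 0, sensorNoiseSd = 0,
                     effectAmplitudeSelf = -1, effectAmplitudeOther = -1,
                     nTrialsPerCondition = 2)
  ses <- simulateSession(cfg)
  elig <- selectHeartbeats(ses$trials, groundTruthEvents(ses$groundTruth))
  ep <- extractHEREpochs(ses$recording, elig, lowpass = NULL,
                         artifactMultiple = Inf)
  avg <- averageHER(ep)
  expect_equal(max(abs(avg@averages$Self - avg@averages$Other)), 0,
               tolerance = 1e-10)
})

test_that("a session survives a round trip through the text container", {
  ses <- simulateSession(smallConfig(9, nChannels = 5,
                                     nTrialsPerCondition = 2))
  d <- file.path(tempdir(), "ses-roundtrip")
  writeSession(ses, d)
  back <- readSession(d)
  expect_equal(sensorData(back$recording), sensorData(ses$recording),
               tolerance = 1e-12)
  expect_equal(back$trials$imagination_onset, ses$trials$imagination_onset)
  expect_equal(rTimes(back$groundTruth), rTimes(ses$groundTruth))
  expect_equal(channelLabels(back$recording), channelLabels(ses$recording))
  unlink(d, recursive = TRUE)
})

test_that("unknown effect sensors are rejected", {
  cfg <- smallConfig(10, effectSensors = c("NOPE1", "NOPE2"))
  expect_error(simulateSession(cfg), "effectSensors")
})
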