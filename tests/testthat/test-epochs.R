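# Toy cardiac sequence used throughout: regular beats every 0.854 s with
# T peaks at onset + 0.300 + 0.854 k inside a 7.0 s imagination period.
toyTrialAndEvents <- function(onset = 10, duration = 7.0, nBeats = 12,
                              ratings = TRUE) {
  tT <- onset + 0.300 + 0.854 * (seq_len(nBeats) - 1)
  rT <- tT - 0.280
  ev <- new("CardiacEvents", rTimes = rT, tTimes = tT,
            valid = rep(TRUE, nBeats),
            exclusionReason = rep("none", nBeats))
  trials <- data.frame(trial = 1L, block = 1L, condition = "Self",
                       fixation_onset = onset - 3.5,
                       instruction_onset = onset - 2.3,
                       imagination_onset = onset,
                       imagination_offset = onset + duration,
                       perspective = if (ratings) 3L else NA_integer_,
                       valence = 0L, arousal = 3L, responded = TRUE)
  list(trials = trials, events = ev)
}

test_that("heartbeat eligibility reproduces the hand enumeration", {
  toy <- toyTrialAndEvents()
  sel <- selectHeartbeats(toy$trials, toy$events)
  expect_equal(sel$tTime - 10,
               c(2.008, 2.862, 3.716, 4.570, 5.424, 6.278),
               tolerance = 1e-9)
  expect_equal(nrow(sel), 6)
})

test_that("a T peak closely followed by the next R peak is dropped", {
  toy <- toyTrialAndEvents()
  ev <- toy$events
  # insert an extra R peak 0.35 s after the third eligible T peak
  tT <- ev@tTimes
  extraR <- tT[5] + 0.35
  rT <- sort(c(ev@rTimes, extraR))
  ins <- which(rT == extraR)
  ev2 <- new("CardiacEvents", rTimes = rT,
             tTimes = append(tT, NA_real_, after = ins - 1),
             valid = append(ev@valid, FALSE, after = ins - 1),
             exclusionReason = append(ev@exclusionReason, "no_t_found",
                                      after = ins - 1))
  sel <- selectHeartbeats(toy$trials, ev2, minNextR = 0.4)
  expect_false(any(abs(sel$tTime - tT[5]) < 1e-9))
  expect_equal(nrow(sel), 5)
})

test_that("trials without complete ratings contribute no heartbeats", {
  toy <- toyTrialAndEvents()
  toy$trials$arousal <- NA_integer_
  expect_equal(nrow(selectHeartbeats(toy$trials, toy$events)), 0)
  toy2 <- toyTrialAndEvents()
  toy2$trials$responded <- FALSE
  expect_equal(nrow(selectHeartbeats(toy2$trials, toy2$events)), 0)
})

test_that("invalid beats are excluded from the selection", {
  toy <- toyTrialAndEvents()
  ev <- toy$events
  ev@valid[4] <- FALSE
  ev@exclusionReason[4] <- "noisy_segment"
  sel <- selectHeartbeats(toy$trials, ev)
  expect_equal(nrow(sel), 5)
})

test_that("epochs have the exact sample arithmetic at 1000 Hz", {
  sf <- 1000
  rec <- new("Recording",
             data = matrix(rnorm(2 * 6 * sf), nrow = 2),
             sfreq = sf, channelLabels = c("A", "B"),
             channelPositions = cbind(x = c(0, 1), y = c(0, 0), z = c(1, 1),
                                      layout2d_x = c(0, 1),
                                      layout2d_y = c(0, 0)),
             aux = list())
  elig <- data.frame(trial = 1L, condition = "Self", tTime = 3.0)
  ep <- extractHEREpochs(rec, elig, lowpass = NULL, artifactMultiple = Inf)
  expect_equal(dim(epochData(ep)), c(1, 2, 501))
  expect_equal(range(epochTimes(ep)), c(-100, 400))
})

test_that("a constant channel passes the low-pass filter unchanged", {
  sf <- 250
  rec <- new("Recording",
             data = matrix(7, nrow = 1, ncol = 6 * sf),
             sfreq = sf, channelLabels = "A",
             channelPositions = cbind(x = 0, y = 0, z = 1,
                                      layout2d_x = 0, layout2d_y = 0),
             aux = list())
  elig <- data.frame(trial = 1L, condition = "Self", tTime = 3.0)
  ep <- extractHEREpochs(rec, elig, lowpass = 30, artifactMultiple = Inf)
  expect_equal(as.vector(epochData(ep)[1, 1, ]),
               rep(7, length(epochTimes(ep))), tolerance = 1e-6)
})

test_that("epochs running off the recording edge are logged as dropped", {
  sf <- 250
  rec <- new("Recording",
             data = matrix(rnorm(2 * sf), nrow = 1),
             sfreq = sf, channelLabels = "A",
             channelPositions = cbind(x = 0, y = 0, z = 1,
                                      layout2d_x = 0, layout2d_y = 0),
             aux = list())
  elig <- data.frame(trial = c(1L, 1L), condition = "Self",
                     tTime = c(1.0, 1.95))
  ep <- extractHEREpochs(rec, elig, lowpass = NULL, artifactMultiple = Inf)
  expect_equal(nrow(epochInfo(ep)), 1)
  expect_equal(ep@dropLog$reason, "recording_edge")
})

test_that("averaging identities hold", {
  sf <- 250
  dat <- matrix(rnorm(2 * 10 * sf), nrow = 2)
  rec <- new("Recording", data = dat, sfreq = sf,
             channelLabels = c("A", "B"),
             channelPositions = cbind(x = c(0, 1), y = c(0, 0), z = c(1, 1),
                                      layout2d_x = c(0, 1),
                                      layout2d_y = c(0, 0)),
             aux = list())
  # two epochs at the same latency: average equals either epoch
  elig <- data.frame(trial = c(1L, 2L), condition = "Self",
                     tTime = c(3, 3))
  avg <- averageHER(extractHEREpochs(rec, elig, lowpass = NULL,
                                     artifactMultiple = Inf))
  ep1 <- extractHEREpochs(rec, elig[1, ], lowpass = NULL,
                          artifactMultiple = Inf)
  expect_equal(avg@averages$Self, epochData(ep1)[1, , ], tolerance = 1e-12)
  expect_error(averageHER(ep1, conditions = "Other"), "no epochs")

  # +v and -v cancel
  ep <- extractHEREpochs(rec, elig, lowpass = NULL, artifactMultiple = Inf)
  flipped <- ep
  flipped@data[2, , ] <- -flipped@data[1, , ]
  avg2 <- averageHER(flipped)
  expect_equal(max(abs(avg2@averages$Self)), 0, tolerance = 1e-12)
})

test_that("cluster amplitudes follow their defining identities", {
  # constant epochs
  dat <- array(0, c(3, 2, 100))
  dat[1, , ] <- 2; dat[2, , ] <- 1; dat[3, , ] <- 3
  ep <- new("HEREpochs", data = dat, times = seq(-100, 400, length.out = 100),
            channelLabels = c("A", "B"),
            epochInfo = data.frame(trial = c(1L, 2L, 2L),
                                   condition = c("Self", "Self", "Self"),
                                   tTime = c(12.008, 12.862, 14.570)),
            sfreq = 200)
  amps <- clusterAmplitude(ep, c("A", "B"), c(100, 300),
                           groupBy = "heartbeat")
  expect_equal(amps$amplitude, c(2, 1, 3))
  byTrial <- clusterAmplitude(ep, c("A", "B"), c(100, 300),
                              groupBy = "trial")
  expect_equal(byTrial$amplitude[byTrial$trial == 2], 2)   # mean of 1 and 3
  expect_error(clusterAmplitude(ep, character(0), c(100, 300)), "sensor")
  expect_error(clusterAmplitude(ep, "A", c(500, 600)), "window")
})

test_that("sub-window grouping keeps exactly the enumerated beats", {
  toy <- toyTrialAndEvents()
  sel <- selectHeartbeats(toy$trials, toy$events)
  dat <- array(rnorm(6 * 1 * 50), c(6, 1, 50))
  ep <- new("HEREpochs", data = dat,
            times = seq(-100, 400, length.out = 50), channelLabels = "A",
            epochInfo = data.frame(trial = sel$trial,
                                   condition = sel$condition,
                                   tTime = sel$tTime),
            sfreq = 100)
  sub <- clusterAmplitude(ep, "A", c(80, 350), groupBy = "subwindow",
                          trials = toy$trials, subwindow = c(2, 3))
  expect_equal(sub$nBeats, 2L)   # beats at 2.008 and 2.862 s post onset
  expect_equal(sub$amplitude,
               mean(apply(dat[1:2, 1, ep@times >= 80 & ep@times <= 350],
                          1, mean)))
})

test_that("amplitude averaging commutes with epoch averaging", {
  set.seed(50)
  dat <- array(rnorm(8 * 3 * 60), c(8, 3, 60))
  ep <- new("HEREpochs", data = dat,
            times = seq(-100, 400, length.out = 60),
            channelLabels = c("A", "B", "C"),
            epochInfo = data.frame(trial = rep(1:2, each = 4),
                                   condition = "Self",
                                   tTime = seq(10, 17, by = 1)),
            sfreq = 120)
  amps <- clusterAmplitude(ep, c("A", "C"), c(100, 300),
                           groupBy = "heartbeat")
  avg <- averageHER(ep)
  mask <- ep@times >= 100 & ep@times <= 300
  ampOfMean <- mean(avg@averages$Self[c(1, 3), mask])
  expect_equal(mean(amps$amplitude), ampOfMean, tolerance = 1e-12)
})

test_that("no eligible epoch's analysis window overlaps the next R peak", {
  ses <- simulateSession(smallConfig(51, nTrialsPerCondition = 6),
                         sensors = FALSE)
  ev <- groundTruthEvents(ses$groundTruth)
  sel <- selectHeartbeats(ses$trials, ev)
  rT <- rTimes(ev)
  for (tt in sel$tTime) {
    nxt <- rT[rT > tt][1]
    if (!is.na(nxt)) expect_gte(nxt - tt, 0.4)
  }
})
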