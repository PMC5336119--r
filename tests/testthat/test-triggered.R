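# One-pair triggered design: continuous 1 kHz carrier, stimuli at 4 Hz.
trigSim <- function(nStimuli = 60, dz = 0.001, whiteSd = 0, seed = 1,
                    epAmp = 0, stimRate = 4, nElec = 4) {
  prot <- injectionProtocol(rbind(c(1, 2)), nElectrodes = nElec,
                            currentAmplitude = 1e-4)
  tr <- matrix(c(10, -10, 4, -4)[seq_len(nElec)], nrow = 1)
  durS <- 0.05 + nStimuli / stimRate + 0.3
  plan <- frequencyPlan(1000, periods = ceiling(durS * 1000))
  ev <- evokedModel(dzFraction = dz, latencyS = 0.007, durationS = 0.011,
                    affectedElectrodes = 1:2, stimRateHz = stimRate,
                    nStimuli = nStimuli, epAmplitudeV = epAmp)
  sim <- simulateTriggered(prot, plan, timingPlan(), phantomModel(tr), ev,
                           noiseModel(whiteSd = whiteSd),
                           amplifierModel(samplingRate = 8000), seed = seed)
  list(sim = sim, prot = prot, plan = plan, evoked = ev)
}

test_that("stimulus trains epoch cleanly and align with ground truth", {
  ts <- trigSim(nStimuli = 20, whiteSd = 5e-7, seed = 2)
  cfg <- demodConfig(1000, bandwidthHz = 500)
  trials <- epochExtract(ts$sim$recording, ts$sim$events, cfg,
                         window = c(-0.05, 0.05), channels = 1:2)
  expect_equal(nTrials(trials), 20L)
  expect_equal(trials@dropped, 0L)
  # epoch t=0 aligns with the STIM events
  ev <- events(ts$sim$events)
  stim <- ev$sample[ev$code == "STIM"]
  expect_equal(stim, round(ts$sim$truth$stimTimes * 8000) + 1L)
  # a stimulus without a full window is dropped with a count
  late <- eventLog(rbind(ev, data.frame(
    sample = nrow(ts$sim$recording@data) - 10L, code = "STIM", payload = 99L)))
  trials2 <- epochExtract(ts$sim$recording, late, cfg,
                          window = c(-0.05, 0.05), channels = 1)
  expect_equal(nTrials(trials2), 20L)
  expect_equal(trials2@dropped, 1L)
  # an OUT_OF_COMPLIANCE event inside a window drops that epoch
  ooc <- eventLog(rbind(ev, data.frame(sample = stim[3] + 5L,
                                       code = "OUT_OF_COMPLIANCE",
                                       payload = 0L)))
  trials3 <- epochExtract(ts$sim$recording, ooc, cfg,
                          window = c(-0.05, 0.05), channels = 1)
  expect_equal(trials3@dropped, 1L)
})

test_that("coherent averaging recovers the A*dz transient closed form", {
  ts <- trigSim(nStimuli = 30, dz = 0.001, whiteSd = 0, seed = 3)
  cfg <- demodConfig(1000, bandwidthHz = 500)
  trials <- epochExtract(ts$sim$recording, ts$sim$events, cfg,
                         window = c(-0.04, 0.05), channels = 1:3)
  evk <- coherentAverage(trials, sigmaSentinel = 1e-12)
  # electrode 1 carries 1 mV: peak ~ A*dz = 1 uV at latency + half duration
  # (the 500 Hz demodulation bandwidth rounds the half-sine peak slightly)
  expect_equal(evk@peak[1], 1e-3 * 0.001, tolerance = 0.07)
  search <- evk@time >= 0 & evk@time <= 0.05
  ipk <- which(search)[which.max(abs(evk@dz[1, search]))]
  expect_equal(evk@time[ipk], 0.007 + 0.011 / 2, tolerance = 0.3)
  # electrode 3 is unaffected: its peak stays tiny next to electrode 1's
  expect_lt(evk@peak[3], 0.05 * evk@peak[1])
  # percent change at the peak: 1 uV on 1 mV ~ 0.1%
  expect_equal(evk@dzPct[1, ipk], 0.1, tolerance = 0.1)
})

test_that("zero-dz triggered runs leave the voltage data bit-identical", {
  prot <- injectionProtocol(rbind(c(1, 2)), nElectrodes = 4,
                            currentAmplitude = 1e-4)
  tr <- matrix(c(10, -10, 4, -4), nrow = 1)
  plan <- frequencyPlan(1000, periods = 6000)
  ev0 <- evokedModel(dzFraction = 0, affectedElectrodes = 1:2,
                     stimRateHz = 4, nStimuli = 10)
  a <- simulateTriggered(prot, plan, timingPlan(), phantomModel(tr), ev0,
                         noiseModel(whiteSd = 1e-6),
                         amplifierModel(samplingRate = 8000), seed = 7)
  b <- simulateRecording(prot, plan, timingPlan(), phantomModel(tr),
                         noiseModel(whiteSd = 1e-6),
                         amplifierModel(samplingRate = 8000), seed = 7)
  expect_identical(a$recording@data, b$recording@data)
  # but STIM events are present only in the triggered run
  expect_gt(sum(events(a$events)$code == "STIM"), 0)
})

test_that("stimulus phases are uniform with respect to the carrier", {
  ts <- trigSim(nStimuli = 1000, dz = 0, whiteSd = 0, stimRate = 40,
                nElec = 2, seed = 11)
  t0 <- (ts$sim$truth$schedule$start[1] - 1) / 8000
  phi <- (2 * pi * 1000 * (ts$sim$truth$stimTimes - t0)) %% (2 * pi)
  R <- Mod(mean(exp(1i * phi)))
  # Rayleigh test: under uniformity P(R > sqrt(-log(alpha)/n)) = alpha
  expect_lt(R, sqrt(-log(0.001) / 1000))
})

test_that("baseline sigma of the average shrinks as 1/sqrt(N)", {
  ts <- trigSim(nStimuli = 240, dz = 0, whiteSd = 3e-6, seed = 5)
  cfg <- demodConfig(1000, bandwidthHz = 500)
  trials <- epochExtract(ts$sim$recording, ts$sim$events, cfg,
                         window = c(-0.04, 0.05), baselineS = 0.035,
                         channels = 1:4)
  expect_equal(nTrials(trials), 240L)
  sub <- function(idx) new("TrialSet",
                           epochs = trials@epochs[idx, , , drop = FALSE],
                           eegEpochs = trials@eegEpochs[idx, , , drop = FALSE],
                           time = trials@time, baselineS = trials@baselineS,
                           sampleRate = trials@sampleRate, dropped = 0L)
  ns <- c(15, 60, 240)
  # average sigma over disjoint trial blocks to tame estimator noise
  sig <- vapply(ns, function(n) {
    blocks <- split(seq_len(240), rep(seq_len(240 / n), each = n))
    mean(vapply(blocks, function(idx)
      mean(coherentAverage(sub(idx))@sigmaPre), numeric(1)))
  }, numeric(1))
  slope <- coef(lm(log(sig) ~ log(ns)))[2]
  expect_equal(unname(slope), -0.5, tolerance = 0.12)
})

test_that("the 3-sigma rule holds its false-positive rate under a null", {
  # synthetic white-noise epochs; single-sample search window so the rule is
  # the plain per-sample 3-sigma test
  nTrialsN <- 20; nCh <- 400; nT <- 101
  set.seed(13)
  ep <- array(rnorm(nTrialsN * nCh * nT, 2.66e-3, 1e-6),
              c(nTrialsN, nCh, nT))
  trials <- new("TrialSet", epochs = ep, eegEpochs = ep * 0,
                time = seq(-0.05, 0.05, length.out = nT), baselineS = 0.05,
                sampleRate = 1000, dropped = 0L)
  evk <- coherentAverage(trials, searchWindowS = c(0.0195, 0.0205))
  rate <- mean(evk@significant)
  # Monte-Carlo oracle for the same rule (estimated sigma, one test sample)
  set.seed(14)
  oracle <- mean(replicate(20000, {
    x <- rnorm(51)
    abs(x[51] - mean(x[1:50])) > 3 * sd(x[1:50])
  }))
  expect_lt(abs(rate - oracle), 0.02)
  expect_lt(rate, 0.05)
  # a wider search window can only raise the false-positive count
  evkWide <- coherentAverage(trials, searchWindowS = c(0, 0.05))
  expect_gte(sum(evkWide@significant), sum(evk@significant))
})

test_that("evoked potentials are recovered and independent of the carrier", {
  ts <- trigSim(nStimuli = 60, dz = 0, whiteSd = 2e-6, epAmp = 20e-6, seed = 6)
  cfg <- demodConfig(1000, bandwidthHz = 500, eegCutoffHz = 100)
  trials <- epochExtract(ts$sim$recording, ts$sim$events, cfg,
                         window = c(-0.05, 0.15), channels = 1:3)
  ep <- eegAverage(trials)
  tm <- trials@time
  template <- ifelse(tm >= 0, sin(2 * pi * 20 * tm) * exp(-tm / 0.03), 0)
  post <- tm > 0 & tm < 0.12
  expect_gt(cor(ep[1, post], template[post]), 0.99)
  expect_equal(max(abs(ep[1, ])), 20e-6, tolerance = 0.15)
  # unaffected channel: no structured EP
  expect_lt(max(abs(ep[3, ])), 0.1 * max(abs(ep[1, ])))

  # doubling the carrier amplitude leaves the EP unchanged (same seed)
  prot <- injectionProtocol(rbind(c(1, 2)), nElectrodes = 4,
                            currentAmplitude = 1e-4)
  tr <- matrix(c(10, -10, 4, -4), nrow = 1)
  durS <- 0.05 + 60 / 4 + 0.3
  mk <- function(ampA) {
    plan <- frequencyPlan(1000, periods = ceiling(durS * 1000),
                          amplitudes = ampA)
    sim <- simulateTriggered(prot, plan, timingPlan(), phantomModel(tr),
                             evokedModel(dzFraction = 0,
                                         affectedElectrodes = 1:2,
                                         stimRateHz = 4, nStimuli = 60,
                                         epAmplitudeV = 20e-6),
                             noiseModel(), amplifierModel(samplingRate = 8000),
                             seed = 21)
    trl <- epochExtract(sim$recording, sim$events, cfg,
                        window = c(-0.05, 0.15), channels = 1)
    eegAverage(trl)
  }
  e1 <- mk(1e-4); e2 <- mk(2e-4)
  expect_equal(e2, e1, tolerance = 1e-4)
})

test_that("degenerate constant baselines get the sigma sentinel", {
  ep <- array(2.66e-3, c(3, 2, 101))
  trials <- new("TrialSet", epochs = ep, eegEpochs = ep * 0,
                time = seq(-0.05, 0.05, length.out = 101), baselineS = 0.05,
                sampleRate = 1000, dropped = 0L)
  evk <- coherentAverage(trials, sigmaSentinel = 1e-15)
  expect_equal(evk@sigmaPre, rep(1e-15, 2))
  expect_false(any(evk@significant))
  expect_error(coherentAverage(new("TrialSet",
                                   epochs = ep[1, , , drop = FALSE],
                                   eegEpochs = ep[1, , , drop = FALSE] * 0,
                                   time = seq(-0.05, 0.05, length.out = 101),
                                   baselineS = 0.05, sampleRate = 1000,
                                   dropped = 0L)), "two trials")
})

test_that("evoked results are written as CSV and JSON", {
  ts <- trigSim(nStimuli = 10, dz = 0.001, whiteSd = 0, seed = 4)
  cfg <- demodConfig(1000, bandwidthHz = 500)
  trials <- epochExtract(ts$sim$recording, ts$sim$events, cfg,
                         window = c(-0.02, 0.03), channels = 1:2)
  evk <- coherentAverage(trials, sigmaSentinel = 1e-12)
  base <- withr::local_tempfile()
  writeEvokedResult(evk, base)
  tab <- read.csv(paste0(base, ".csv"))
  expect_equal(sort(unique(tab$channel)), 1:2)
  j <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  expect_equal(j$n_trials, nTrials(trials))
  expect_length(j$channels$snr, 2L)
})
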