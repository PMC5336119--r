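# Shared builders for small synthetic objects used across the suite.

tinyProtocol <- function(currentA = 1e-4) {
  injectionProtocol(rbind(c(1, 2), c(3, 4)), nElectrodes = 4,
                    currentAmplitude = currentA)
}

tinyTransfer <- function() {
  rbind(c(10, -10, 4, -4),
        c(3, -3, 12, -12))
}

tinySim <- function(nFrames = 2, seed = 1, noise = noiseModel(),
                    freqHz = 2000, periods = 200, fs = 16000,
                    phantom = phantomModel(tinyTransfer()), evoked = NULL) {
  simulateRecording(tinyProtocol(), frequencyPlan(freqHz, periods = periods),
                    timingPlan(periods / freqHz), phantom, noise,
                    amplifierModel(samplingRate = fs), nFrames = nFrames,
                    seed = seed, evoked = evoked)
}

# Independent quadrature (lock-in) amplitude estimate: multiply by sin/cos at
# the carrier and average over the window. Oracle for the Hilbert path.
lockinAmp <- function(x, fs, f) {
  t <- (seq_along(x) - 1) / fs
  i <- 2 * mean(x * sin(2 * pi * f * t))
  q <- 2 * mean(x * cos(2 * pi * f * t))
  sqrt(i^2 + q^2)
}

# Measurements table straight from a transfer table (bypasses sample-domain
# simulation): amplitude = I * |Z| * gain, one frame.
transferMeasurements <- function(protocol, transfer, currentA, freqHz = 2000,
                                 gain = 1, nFrames = 1) {
  np <- nrow(transfer); ne <- ncol(transfer)
  do.call(rbind, lapply(seq_len(nFrames), function(fr)
    data.frame(frame = fr,
               pair = rep(seq_len(np), ne),
               electrode = rep(seq_len(ne), each = np),
               freq_hz = freqHz, freq_idx = 1L,
               amp_v = as.vector(abs(transfer)) * currentA * gain,
               phase_rad = as.vector(ifelse(transfer >= 0, 0, pi)),
               valid = TRUE)))
}
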