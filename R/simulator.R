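## Synthetic raw-recording generator: switched sinusoidal carriers routed through
## a phantom's transfer impedances, an amplifier anti-aliasing gain, additive
## white noise, random-walk amplitude drift and (optionally) stimulus-locked
## impedance transients, together with a coded trigger channel.

#' Run an expression under a local RNG seed, restoring the caller's RNG state
#' @noRd
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Anti-aliasing filter magnitude gain
#'
#' Magnitude response of the configured amplifier front-end model, normalised to
#' unity at DC. \code{"first_order"}: single-pole RC, gain 1/sqrt(2) at the
#' cutoff. \code{"butterworth_n"}: order-n Butterworth low-pass, also -3 dB at
#' the cutoff. \code{"sinc_power_n"}: CIC-style \code{|sinc(f/cutoff)|^n} with
#' its first null at the cutoff.
#'
#' @param amplifier an \linkS4class{AmplifierModel}.
#' @param f frequency in Hz (vectorised, f >= 0).
#' @return dimensionless gain in (0, 1].
#' @export
gainFilter <- function(amplifier, f) {
  if (any(f < 0)) stop("frequency must be >= 0")
  fc <- amplifier@cutoffHz
  n <- amplifier@filterOrder
  switch(amplifier@filterType,
    first_order   = 1 / sqrt(1 + (f / fc)^2),
    butterworth_n = 1 / sqrt(1 + (f / fc)^(2 * n)),
    sinc_power_n  = {
      x <- pi * f / fc
      g <- ifelse(f == 0, 1, abs(sin(x) / x))^n
      g
    },
    stop("unknown filter type: ", amplifier@filterType))
}

#' Amplifier model constructor
#'
#' @param samplingRate samples per second (16 kHz and 25 kHz are the two
#'   EEG-system defaults emulated).
#' @param filterType,cutoffHz,filterOrder anti-aliasing model, see
#'   \code{\link{gainFilter}}.
#' @param inputRangeV one-sided input range (V); the file container quantises to
#'   \code{2 * inputRangeV / 2^resolutionBits} per LSB.
#' @param resolutionBits ADC bits (24 for the emulated EEG systems).
#' @export
amplifierModel <- function(samplingRate = 16000, filterType = "first_order",
                           cutoffHz = 3200, filterOrder = 1,
                           inputRangeV = 0.262, resolutionBits = 24) {
  new("AmplifierModel", samplingRate = samplingRate, filterType = filterType,
      cutoffHz = cutoffHz, filterOrder = filterOrder,
      inputRangeV = inputRangeV, resolutionBits = resolutionBits)
}

#' Container quantisation step (volts per LSB)
#' @param amplifier an \linkS4class{AmplifierModel}.
#' @export
quantisationStep <- function(amplifier) {
  2 * amplifier@inputRangeV / 2^amplifier@resolutionBits
}

#' Noise model constructor
#' @param whiteSd per-sample additive Gaussian SD, volts.
#' @param driftRate random-walk SD on per-channel carrier amplitude, V/sqrt(s).
#' @export
noiseModel <- function(whiteSd = 0, driftRate = 0) {
  new("NoiseModel", whiteSd = whiteSd, driftRate = driftRate)
}

#' Evoked (stimulus-locked impedance transient) model constructor
#' @param dzFraction fractional impedance change at pulse peak.
#' @param latencyS onset after the stimulus, s.
#' @param durationS half-sine pulse duration, s.
#' @param affectedElectrodes electrode indices carrying the transient.
#' @param stimRateHz stimulus rate, Hz.
#' @param nStimuli stimuli in the train.
#' @param epAmplitudeV peak evoked-potential amplitude added at baseband, V.
#' @export
evokedModel <- function(dzFraction = 0.001, latencyS = 0.007, durationS = 0.011,
                        affectedElectrodes = integer(), stimRateHz = 2,
                        nStimuli = 60, epAmplitudeV = 0) {
  new("EvokedModel", dzFraction = dzFraction, latencyS = latencyS,
      durationS = durationS, affectedElectrodes = as.integer(affectedElectrodes),
      stimRateHz = stimRateHz, nStimuli = as.integer(nStimuli),
      epAmplitudeV = epAmplitudeV)
}

#' Dispersive tissue impedance model
#'
#' Relative impedance magnitude versus frequency for a dispersive (tissue-like)
#' load: an exponential-saturation drop
#' \code{r(f) = 1 - D * (1 - exp(-f / tauHz))}, with D calibrated so the
#' fractional decrease from \code{refHz} to \code{atHz} is exactly \code{drop},
#' and the returned gain normalised to 1 at \code{refHz}. With the default
#' \code{refHz = 0} the drop is measured from DC. A purely resistive load is
#' \code{drop = 0}.
#'
#' @param drop fractional impedance decrease from \code{refHz} to \code{atHz}
#'   (0.15 emulates healthy cortical tissue over 0-250 Hz; ischaemic tissue is
#'   shallower, about 0.07).
#' @param atHz frequency at which the stated drop is reached.
#' @param tauHz exponential corner of the drop.
#' @param refHz reference frequency: gain 1 there, and the drop is measured
#'   relative to it (use the sweep's reference frequency to make a measured
#'   spectrum carry the declared drop exactly).
#' @return function of frequency (Hz) returning the gain.
#' @export
dispersionModel <- function(drop = 0.15, atHz = 250, tauHz = 60, refHz = 0) {
  stopifnot(drop >= 0, drop < 1, atHz > refHz, tauHz > 0)
  e <- function(f) 1 - exp(-f / tauHz)
  D <- drop / (e(atHz) - e(refHz) + drop * e(refHz))
  r <- function(f) 1 - D * e(f)
  ref <- r(refHz)
  function(f) r(f) / ref
}

#' Phantom model constructor
#'
#' @param transfer signed transfer-impedance matrix, pairs x electrodes, ohms.
#' @param dispersion gain function of frequency (default: frequency-flat, i.e.
#'   purely resistive).
#' @export
phantomModel <- function(transfer, dispersion = function(f) rep(1, length(f))) {
  new("PhantomModel", transfer = as.matrix(transfer),
      nElectrodes = ncol(transfer), dispersion = dispersion)
}

#' White-noise level that yields a target demodulated amplitude SD
#'
#' For additive white noise of per-sample SD \code{sigma}, the demodulated
#' amplitude of a strong carrier estimated as the mean Hilbert envelope over a
#' window of N samples has SD \code{sigma * sqrt(2 / N)} (the in-phase
#' narrowband noise component averaged over the window; independent of the
#' band-pass bandwidth). This inverts that relation.
#'
#' @param demodSd target demodulated amplitude SD, volts.
#' @param samplingRate samples per second.
#' @param windowS averaging-window length in seconds (after settle trimming).
#' @return per-sample white noise SD, volts.
#' @export
whiteSdForDemodSd <- function(demodSd, samplingRate, windowS) {
  n <- samplingRate * windowS
  demodSd * sqrt(n / 2)
}

## Build the per-frame frequency-block order.
blockOrder <- function(plan, nFrames) {
  nf <- length(plan@frequencies)
  base <- switch(plan@ordering,
    fixed = seq_len(nf),
    ascending = order(plan@frequencies),
    descending = order(plan@frequencies, decreasing = TRUE),
    random = NULL)
  lapply(seq_len(nFrames), function(i)
    if (is.null(base)) sample.int(nf) else base)
}

## Ground-truth injection schedule: one row per (frame, block, pair) span.
## leadIn: silent samples before INJ_START; blocks start 2*pulse widths later.
buildSchedule <- function(protocol, plan, timing, fs, nFrames, order, leadIn) {
  np <- nPairs(protocol)
  gapN <- round(timing@gapS * fs)
  rows <- vector("list", nFrames * length(plan@frequencies) * np)
  cur <- leadIn + 9L   # INJ_START at leadIn + 1, first span 8 samples later
  k <- 0L
  for (fr in seq_len(nFrames)) {
    for (q in order[[fr]]) {
      f <- plan@frequencies[q]
      L <- round(injectionDuration(timing, f, plan@periods[q]) * fs)
      if (L < 8L) stop("injection span shorter than 8 samples")
      for (p in seq_len(np)) {
        k <- k + 1L
        rows[[k]] <- c(fr, q, p, cur, cur + L)
        cur <- cur + L + gapN
      }
    }
  }
  m <- do.call(rbind, rows)
  data.frame(frame = m[, 1], freq_idx = m[, 2], pair = m[, 3],
             start = m[, 4], stop = m[, 5])  # half-open [start, stop)
}

## Events for a schedule: INJ_START, FREQ_CHANGE at each block start,
## PAIR_SWITCH at each subsequent injection, INJ_STOP after the last span.
scheduleEvents <- function(sched, leadIn) {
  blockFirst <- sched$pair == 1L
  data.frame(
    sample = c(leadIn + 1L, sched$start, max(sched$stop) + 1L),
    code = c("INJ_START",
             ifelse(blockFirst, "FREQ_CHANGE", "PAIR_SWITCH"),
             "INJ_STOP"),
    payload = c(0L, ifelse(blockFirst, sched$freq_idx, sched$pair), 0L))
}

#' Simulate a raw multi-channel EIT recording
#'
#' Synthesises per-sample electrode voltages for a full acquisition: for every
#' injection span (frame, frequency block, pair) the voltage on electrode e is
#' \code{A_f * Z[pair, e] * dispersion(f) * gainFilter(f) * sin(2 pi f t)} with
#' the carrier phase reset to zero at each switch, plus a per-channel
#' random-walk amplitude drift and additive white noise. Controller events
#' (injection start/stop, pair switches, frequency changes) are emitted at
#' exact sample indices and encoded on an integer trigger channel.
#'
#' @param protocol \linkS4class{InjectionProtocol}.
#' @param plan \linkS4class{FrequencyPlan} (a single-frequency plan for
#'   standard mode).
#' @param timing \linkS4class{TimingPlan}.
#' @param phantom \linkS4class{PhantomModel}.
#' @param noise \linkS4class{NoiseModel}.
#' @param amplifier \linkS4class{AmplifierModel}.
#' @param nFrames complete protocol repetitions.
#' @param seed RNG seed (restored afterwards); NULL uses the current RNG state.
#' @param evoked optional \linkS4class{EvokedModel}: adds a stimulus train with
#'   impedance transients (see \code{\link{simulateTriggered}}).
#' @param leadInS silence before the injection-start marker, seconds.
#' @param oocInjections optional data.frame (frame, freq_idx, pair): spans to
#'   flag with an out-of-compliance event at mid-span.
#' @return list with elements \code{recording} (\linkS4class{RawRecording}),
#'   \code{events} (\linkS4class{EventLog}) and \code{truth} (ground-truth
#'   schedule, per-span carrier amplitudes and stimulus times).
#' @export
simulateRecording <- function(protocol, plan, timing, phantom,
                              noise = noiseModel(), amplifier = amplifierModel(),
                              nFrames = 1, seed = NULL, evoked = NULL,
                              leadInS = 0.005, oocInjections = NULL) {
  fs <- amplifier@samplingRate
  ne <- nElectrodes(protocol)
  if (ne != phantom@nElectrodes) stop("protocol and phantom electrode counts differ")
  if (nrow(phantom@transfer) != nPairs(protocol))
    stop("phantom transfer table must have one row per injection pair")
  fmax <- max(plan@frequencies)
  if (fs < 4 * fmax) stop("sampling rate below 4x the maximum carrier frequency")
  if (fs < 8 * fmax) warning("sampling rate below 8x the maximum carrier frequency")

  withSeed(seed, {
    ord <- blockOrder(plan, nFrames)
    leadIn <- round(leadInS * fs)
    sched <- buildSchedule(protocol, plan, timing, fs, nFrames, ord, leadIn)
    nSamples <- max(sched$stop) + leadIn + 8L
    dat <- matrix(0, nSamples, ne)

    # stimulus times (uniform random offset vs carrier phase), drawn from a
    # derived seed so that an evoked model with dzFraction = 0 leaves the
    # voltage data bit-identical to the non-triggered simulation
    stimTimes <- numeric(0)
    if (!is.null(evoked)) {
      f1 <- plan@frequencies[sched$freq_idx[1L]]
      span1 <- sched[1L, ]
      jitterSeed <- if (is.null(seed)) NULL else (seed + 77003L) %% .Machine$integer.max
      jit <- withSeed(jitterSeed, runif(evoked@nStimuli, 0, 1 / f1))
      base <- (span1$start - 1) / fs + 0.05 + (seq_len(evoked@nStimuli) - 1) / evoked@stimRateHz
      stimTimes <- base + jit
      lastNeeded <- max(stimTimes) + evoked@latencyS + evoked@durationS + 0.05
      if (lastNeeded > (span1$stop - 1) / fs)
        stop("stimulus train does not fit inside the first injection span")
    }

    drift <- rep(0, ne)
    ampTruth <- matrix(NA_real_, nrow(sched), ne)
    for (i in seq_len(nrow(sched))) {
      q <- sched$freq_idx[i]
      f <- plan@frequencies[q]
      g <- gainFilter(amplifier, f) * phantom@dispersion(f)
      ampE <- plan@amplitudes[q] * phantom@transfer[sched$pair[i], ] * g
      idx <- sched$start[i]:(sched$stop[i] - 1L)
      tRel <- (seq_along(idx) - 1L) / fs
      if (noise@driftRate > 0)
        drift <- drift + rnorm(ne, 0, noise@driftRate * sqrt(length(idx) / fs))
      amps <- ampE + drift
      ampTruth[i, ] <- amps
      wave <- sin(2 * pi * f * tRel)
      seg <- tcrossprod(wave, amps)   # samples x electrodes
      if (!is.null(evoked) && length(stimTimes) &&
          i == 1L && abs(evoked@dzFraction) > 0) {
        env <- dzEnvelope(tRel + (sched$start[i] - 1L) / fs, stimTimes, evoked)
        ae <- evoked@affectedElectrodes
        seg[, ae] <- seg[, ae] * (1 + evoked@dzFraction * env)
      }
      dat[idx, ] <- seg
    }

    if (!is.null(evoked) && length(stimTimes) && evoked@epAmplitudeV != 0) {
      tAll <- (seq_len(nSamples) - 1L) / fs
      ep <- epTemplateSum(tAll, stimTimes, evoked@epAmplitudeV)
      for (e in evoked@affectedElectrodes) dat[, e] <- dat[, e] + ep
    }

    if (noise@whiteSd > 0)       # column-wise to halve the peak footprint
      for (e in seq_len(ne))
        dat[, e] <- dat[, e] + rnorm(nSamples, 0, noise@whiteSd)

    ev <- scheduleEvents(sched, leadIn)
    if (!is.null(evoked) && length(stimTimes))
      ev <- rbind(ev, data.frame(sample = round(stimTimes * fs) + 1L,
                                 code = "STIM", payload = seq_along(stimTimes)))
    if (!is.null(oocInjections)) {
      for (j in seq_len(nrow(oocInjections))) {
        hit <- sched$frame == oocInjections$frame[j] &
          sched$freq_idx == oocInjections$freq_idx[j] &
          sched$pair == oocInjections$pair[j]
        s <- sched[hit, , drop = FALSE]
        if (nrow(s) != 1L) stop("oocInjections row does not match one span")
        ev <- rbind(ev, data.frame(
          sample = as.integer(floor((s$start + s$stop) / 2)),
          code = "OUT_OF_COMPLIANCE", payload = 0L))
      }
    }
    ev <- ev[order(ev$sample), , drop = FALSE]
    rownames(ev) <- NULL
    log <- eventLog(ev)
    trig <- encodeEvents(log, nSamples)

    rec <- new("RawRecording", data = dat, triggers = trig, samplingRate = fs,
               channelNames = paste0("E", seq_len(ne)))
    list(recording = rec, events = log,
         truth = list(schedule = sched, amplitudes = ampTruth,
                      stimTimes = stimTimes, order = ord, leadIn = leadIn))
  })
}

## Summed half-sine impedance pulses (unit peak) at absolute times t.
dzEnvelope <- function(t, stimTimes, evoked) {
  env <- numeric(length(t))
  for (s in stimTimes) {
    a <- s + evoked@latencyS
    sel <- t >= a & t < a + evoked@durationS
    if (any(sel)) env[sel] <- env[sel] + sin(pi * (t[sel] - a) / evoked@durationS)
  }
  env
}

## Summed damped-sine evoked-potential templates (peak = amp) at times t.
epTemplateSum <- function(t, stimTimes, amp) {
  out <- numeric(length(t))
  # unit-peak template: sin(2 pi 20 tau) exp(-tau / 0.03), peak ~ at tau = 0.011
  tau0 <- seq(0, 0.2, by = 1e-4)
  peak <- max(sin(2 * pi * 20 * tau0) * exp(-tau0 / 0.03))
  for (s in stimTimes) {
    sel <- t >= s & t < s + 0.2
    tau <- t[sel] - s
    out[sel] <- out[sel] + amp * sin(2 * pi * 20 * tau) * exp(-tau / 0.03) / peak
  }
  out
}

#' Simulate a triggered-averaging recording
#'
#' Continuous current injection through (typically) one pair while a stimulus
#' train runs; each stimulus scales the transfer impedance of the affected
#' electrodes by \code{1 + dzFraction * pulse(t - tStim)} (half-sine pulse) and
#' optionally adds a baseband evoked potential. Stimulus times carry a uniform
#' random offset relative to the carrier phase, and appear as STIM events.
#'
#' @inheritParams simulateRecording
#' @param evoked an \linkS4class{EvokedModel} (required).
#' @return as \code{\link{simulateRecording}}.
#' @export
simulateTriggered <- function(protocol, plan, timing, phantom, evoked,
                              noise = noiseModel(), amplifier = amplifierModel(),
                              nFrames = 1, seed = NULL, leadInS = 0.005) {
  stopifnot(is(evoked, "EvokedModel"))
  simulateRecording(protocol, plan, timing, phantom, noise, amplifier,
                    nFrames = nFrames, seed = seed, evoked = evoked,
                    leadInS = leadInS)
}
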