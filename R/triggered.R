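## Coherent (stimulus-triggered) averaging of impedance transients and
## simultaneous evoked potentials.

#' Extract stimulus-locked epochs from a recording
#'
#' Demodulates the requested channels continuously (band-pass + Hilbert
#' envelope) and low-pass filters the raw signal for the simultaneous EEG, then
#' cuts one epoch per STIM event. Epochs whose window crosses an injection-span
#' boundary, or that overlap an OUT_OF_COMPLIANCE event, are dropped and
#' counted.
#'
#' @param recording a \linkS4class{RawRecording}.
#' @param log an \linkS4class{EventLog} containing STIM events.
#' @param config a \code{\link{demodConfig}} (carrier and bandwidth).
#' @param window epoch window relative to the stimulus, seconds
#'   (e.g. \code{c(-0.25, 0.25)} for the 500 ms window).
#' @param baselineS pre-stimulus baseline length, seconds.
#' @param channels channel indices (default all).
#' @param segments optional segment table; when given, epochs must fall inside a
#'   single injection span.
#' @return a \linkS4class{TrialSet}.
#' @export
epochExtract <- function(recording, log, config, window = c(-0.25, 0.25),
                         baselineS = 0.010, channels = NULL, segments = NULL) {
  fs <- recording@samplingRate
  if (is.null(channels)) channels <- seq_len(ncol(recording@data))
  ev <- events(log)
  stim <- ev$sample[ev$code == "STIM"]
  if (length(stim) == 0L) stop("no STIM events in log")
  ooc <- ev$sample[ev$code == "OUT_OF_COMPLIANCE"]
  pre <- round(-window[1L] * fs)
  post <- round(window[2L] * fs)

  amp <- demodulateChannels(recording, config, channels)
  eeg <- extractEEG(recording@data[, channels, drop = FALSE], fs,
                    config$eegCutoffHz, config$carrierHz, config$bandwidthHz)

  keep <- logical(length(stim))
  for (i in seq_along(stim)) {
    a <- stim[i] - pre; b <- stim[i] + post
    ok <- a >= 1L && b <= nrow(amp)
    if (ok && !is.null(segments)) {
      inSpan <- segments$start <= a & segments$stop >= b
      ok <- any(inSpan)
    }
    if (ok && length(ooc)) ok <- !any(ooc >= a & ooc <= b)
    keep[i] <- ok
  }
  if (!any(keep)) stop("no usable epochs")
  stim <- stim[keep]
  nT <- length(stim); nC <- length(channels); nS <- pre + post + 1L
  ep <- array(NA_real_, c(nT, nC, nS))
  epE <- array(NA_real_, c(nT, nC, nS))
  for (i in seq_len(nT)) {
    idx <- (stim[i] - pre):(stim[i] + post)
    ep[i, , ] <- t(amp[idx, , drop = FALSE])
    epE[i, , ] <- t(eeg[idx, , drop = FALSE])
  }
  new("TrialSet", epochs = ep, eegEpochs = epE,
      time = (seq_len(nS) - 1L - pre) / fs, baselineS = baselineS,
      sampleRate = fs, dropped = sum(!keep))
}

#' @rdname epochExtract
#' @param x a TrialSet.
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname epochExtract
#' @export
setMethod("nTrials", "TrialSet", function(x) dim(x@epochs)[1L])

setMethod("show", "TrialSet", function(object) {
  d <- dim(object@epochs)
  cat(sprintf(
    "TrialSet: %d trials x %d channels x %d samples (%.0f..%.0f ms), %d dropped\n",
    d[1], d[2], d[3], 1000 * object@time[1L], 1000 * object@time[d[3]],
    object@dropped))
})

#' Coherent average of stimulus-locked impedance epochs
#'
#' Averages the demodulated-amplitude epochs across trials, subtracts the mean
#' of the pre-stimulus baseline window, and computes per channel the baseline
#' SD of the *averaged* trace (sigma_pre), the peak |dz| in the post-stimulus
#' search window, the triggered SNR (peak / sigma_pre) and the 3-sigma
#' significance flag.
#'
#' @param trialset a \linkS4class{TrialSet}.
#' @param searchWindowS post-stimulus window searched for the peak, seconds.
#' @param sigmaSentinel sigma_pre replacement when the baseline variance is
#'   exactly zero (degenerate input).
#' @return an \linkS4class{EvokedResult}.
#' @export
coherentAverage <- function(trialset, searchWindowS = c(0, 0.05),
                            sigmaSentinel = .Machine$double.eps) {
  if (nTrials(trialset) < 2L) stop("need at least two trials")
  tm <- trialset@time
  avg <- apply(trialset@epochs, c(2, 3), mean)      # channels x time
  basel <- tm >= -trialset@baselineS & tm < 0
  base <- rowMeans(avg[, basel, drop = FALSE])
  dz <- avg - base
  sigma <- apply(dz[, basel, drop = FALSE], 1, sd)
  degenerate <- sigma == 0
  sigma[degenerate] <- sigmaSentinel
  search <- tm >= searchWindowS[1L] & tm <= searchWindowS[2L]
  if (!any(search)) stop("search window contains no samples")
  peak <- apply(abs(dz[, search, drop = FALSE]), 1, max)
  snr <- peak / sigma
  new("EvokedResult", dz = dz, dzPct = 100 * dz / base, sigmaPre = sigma,
      peak = peak, snr = snr, significant = peak > 3 * sigma, time = tm,
      nTrials = nTrials(trialset))
}

#' Mean evoked potential from the EEG epochs
#'
#' The same baseline-subtracted trial average applied to the low-passed
#' (baseband) epochs; no significance rule.
#'
#' @param trialset a \linkS4class{TrialSet}.
#' @return matrix channels x time, volts.
#' @export
eegAverage <- function(trialset) {
  tm <- trialset@time
  avg <- apply(trialset@eegEpochs, c(2, 3), mean)
  basel <- tm >= -trialset@baselineS & tm < 0
  avg - rowMeans(avg[, basel, drop = FALSE])
}

setMethod("show", "EvokedResult", function(object) {
  cat(sprintf(
    "EvokedResult: %d channels x %d samples from %d trials; %d significant (>3 sigma)\n",
    nrow(object@dz), ncol(object@dz), object@nTrials, sum(object@significant)))
})

#' Write an evoked result as CSV + JSON summary
#'
#' CSV columns: channel, time_ms, dz_v, dz_pct. JSON: per-channel peak,
#' sigma_pre, snr, significance.
#'
#' @param evoked an \linkS4class{EvokedResult}.
#' @param pathBase path without extension.
#' @export
writeEvokedResult <- function(evoked, pathBase) {
  nC <- nrow(evoked@dz); nS <- ncol(evoked@dz)
  tab <- data.frame(channel = rep(seq_len(nC), each = nS),
                    time_ms = rep(1000 * evoked@time, nC),
                    dz_v = as.vector(t(evoked@dz)),
                    dz_pct = as.vector(t(evoked@dzPct)))
  write.csv(tab, paste0(pathBase, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_trials = evoked@nTrials,
         channels = data.frame(channel = seq_len(nC), peak_v = evoked@peak,
                               sigma_pre_v = evoked@sigmaPre, snr = evoked@snr,
                               significant = evoked@significant)),
    paste0(pathBase, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(pathBase)
}
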