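## Demodulation: zero-phase IIR band-pass around the carrier, Hilbert-transform
## envelope/phase extraction, simultaneous EEG recovery by low-pass filtering,
## and per-segment boundary-voltage measurement.

#' Demodulation configuration
#'
#' @param carrierHz carrier frequency.
#' @param bandwidthHz full width of the band-pass around the carrier; default
#'   \code{min(carrierHz, 1000)} so the band stays positive and the time
#'   resolution matches a 1 kHz bandwidth at high carriers.
#' @param filterOrder Butterworth prototype order (per band edge).
#' @param eegCutoffHz low-pass cutoff for the simultaneous EEG signal.
#' @return a list used by the measurement functions.
#' @export
demodConfig <- function(carrierHz, bandwidthHz = min(carrierHz, 1000),
                        filterOrder = 5, eegCutoffHz = 100) {
  if (bandwidthHz <= 0 || bandwidthHz >= 2 * carrierHz)
    stop("bandwidth must be in (0, 2*carrier)")
  list(carrierHz = carrierHz, bandwidthHz = bandwidthHz,
       filterOrder = filterOrder, eegCutoffHz = eegCutoffHz)
}

## Butterworth band-pass design with a stability check on the denominator roots.
designBandpass <- function(fs, carrierHz, bandwidthHz, order) {
  lo <- carrierHz - bandwidthHz / 2
  hi <- carrierHz + bandwidthHz / 2
  nyq <- fs / 2
  if (lo <= 0 || hi >= nyq) stop("band edges outside (0, Nyquist)")
  flt <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  r <- polyroot(rev(flt$a))
  if (any(Mod(r) >= 1 - 1e-10)) stop("unstable band-pass design; reduce order")
  flt
}

#' Zero-phase band-pass filter around a carrier
#'
#' Forward-backward (zero net phase shift) Butterworth band-pass centred on the
#' carrier.
#'
#' @param x numeric vector or samples-x-channels matrix.
#' @param fs sampling rate, Hz.
#' @param config a \code{\link{demodConfig}}.
#' @return filtered signal, same shape as \code{x}.
#' @export
bandpassZeroPhase <- function(x, fs, config) {
  flt <- designBandpass(fs, config$carrierHz, config$bandwidthHz,
                        config$filterOrder)
  applyFiltfilt(flt, x)
}

applyFiltfilt <- function(flt, x) {
  if (is.matrix(x)) {
    out <- x
    for (j in seq_len(ncol(x)))
      out[, j] <- signal::filtfilt(flt, x[, j])
    out
  } else {
    signal::filtfilt(flt, x)
  }
}

#' Analytic signal via the frequency domain
#'
#' Lengths with a large prime factor are zero-padded to the next 2-3-5-smooth
#' length and truncated after the transform (the mixed-radix FFT is otherwise
#' quadratic on them); the padding perturbs only the window edges, which the
#' callers trim.
#' @noRd
analyticSignal <- function(x) {
  n0 <- length(x)
  if (largestPrimeFactor(n0) > 127L) {
    np <- stats::nextn(n0, c(2, 3, 5))
    return(analyticSignal(c(x, numeric(np - n0)))[seq_len(n0)])
  }
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Hilbert envelope and unwrapped phase
#'
#' Amplitude (modulus of the analytic signal) and unwrapped instantaneous phase
#' of a narrowband (band-passed) signal. For \code{A * sin(2 pi f t)} the
#' envelope is A and the phase advances at \code{2 pi f} per second.
#'
#' @param x numeric vector (a band-passed segment).
#' @return list with \code{amplitude} and \code{phase} vectors.
#' @export
hilbertEnvelope <- function(x) {
  a <- analyticSignal(x)
  list(amplitude = Mod(a), phase = unwrapPhase(Arg(a)))
}

largestPrimeFactor <- function(n) {
  n <- as.integer(n)
  lp <- 1L; p <- 2L
  while (n > 1L && p * p <= n) {
    while (n %% p == 0L) { n <- n %/% p; lp <- p }
    p <- p + 1L
  }
  if (n > 1L) lp <- n
  lp
}

unwrapPhase <- function(p) {
  d <- diff(p)
  jump <- cumsum(c(0, round(d / (2 * pi))))
  p - 2 * pi * jump
}

#' Extract the simultaneous EEG signal
#'
#' Zero-phase low-pass of the raw (unsegmented) channel; the carrier is far
#' above the cutoff and is suppressed to the filter's stopband floor. DC is
#' preserved.
#'
#' @param x numeric vector or samples-x-channels matrix of raw voltages.
#' @param fs sampling rate.
#' @param eegCutoffHz low-pass cutoff, must sit below the carrier band.
#' @param carrierHz optional carrier for the precondition check.
#' @param bandwidthHz optional carrier bandwidth for the precondition check.
#' @param order filter order.
#' @export
extractEEG <- function(x, fs, eegCutoffHz = 100, carrierHz = NULL,
                       bandwidthHz = 0, order = 5) {
  if (!is.null(carrierHz) && eegCutoffHz >= carrierHz - bandwidthHz / 2)
    stop("EEG cutoff overlaps the carrier band")
  flt <- signal::butter(order, eegCutoffHz / (fs / 2), type = "low")
  applyFiltfilt(flt, x)
}

#' Demodulate whole channels continuously
#'
#' Band-pass + Hilbert envelope over a full recording, used by triggered
#' averaging where a continuous impedance signal is needed.
#'
#' @param recording a \linkS4class{RawRecording}.
#' @param config a \code{\link{demodConfig}}.
#' @param channels channel indices (default all).
#' @return samples x channels matrix of demodulated amplitude (V).
#' @export
demodulateChannels <- function(recording, config, channels = NULL) {
  if (is.null(channels)) channels <- seq_len(ncol(recording@data))
  bp <- bandpassZeroPhase(recording@data[, channels, drop = FALSE],
                          recording@samplingRate, config)
  out <- bp
  for (j in seq_len(ncol(bp)))
    out[, j] <- Mod(analyticSignal(bp[, j]))
  out
}

#' Measure all segments of a recording
#'
#' For every segment (one injection span), the full span of each channel is
#' band-pass filtered at the segment's carrier, the Hilbert envelope taken, and
#' the measurement formed as the mean envelope over the trimmed window
#' (amplitude, the modulus) together with the circular-mean phase offset
#' relative to a carrier referenced to zero phase at span onset.
#'
#' @param recording a \linkS4class{RawRecording}.
#' @param segments segment table from \code{\link{segmentRecording}}.
#' @param bandwidthHz full demodulation bandwidth, or NULL for the per-carrier
#'   default \code{min(carrier, 1000)}.
#' @param filterOrder band-pass Butterworth order.
#' @param minPeriods minimum carrier periods required in the trimmed window.
#' @return data.frame of measurements: \code{frame}, \code{pair},
#'   \code{electrode}, \code{freq_hz}, \code{amp_v}, \code{phase_rad},
#'   \code{valid}.
#' @export
measureSegments <- function(recording, segments, bandwidthHz = NULL,
                            filterOrder = 5, minPeriods = 8) {
  fs <- recording@samplingRate
  ne <- ncol(recording@data)
  filters <- list()
  n <- nrow(segments)
  amp <- matrix(NA_real_, n, ne)
  ph <- matrix(NA_real_, n, ne)
  for (i in seq_len(n)) {
    f <- segments$freq_hz[i]
    winN <- segments$mstop[i] - segments$mstart[i]
    if (winN < minPeriods * fs / f)
      stop(sprintf("segment %d too short: %d samples < %g carrier periods",
                   i, winN, minPeriods))
    key <- as.character(f)
    if (is.null(filters[[key]])) {
      bw <- if (is.null(bandwidthHz)) min(f, 1000) else bandwidthHz
      filters[[key]] <- designBandpass(fs, f, bw, filterOrder)
    }
    idx <- segments$start[i]:(segments$stop[i] - 1L)
    mrel <- (segments$mstart[i] - segments$start[i] + 1L):
            (segments$mstop[i] - segments$start[i])
    seg <- recording@data[idx, , drop = FALSE]
    tRef <- 2 * pi * f * (seq_along(idx) - 1L) / fs
    for (e in seq_len(ne)) {
      bp <- signal::filtfilt(filters[[key]], seg[, e])
      an <- analyticSignal(bp)
      amp[i, e] <- mean(Mod(an)[mrel])
      dphi <- Arg(an)[mrel] - (tRef[mrel] - pi / 2)  # sin carrier: phase -pi/2 at onset
      ph[i, e] <- Arg(mean(exp(1i * dphi)))
    }
  }
  data.frame(frame = rep(segments$frame, ne),
             pair = rep(segments$pair, ne),
             electrode = rep(seq_len(ne), each = n),
             freq_hz = rep(segments$freq_hz, ne),
             freq_idx = rep(segments$freq_idx, ne),
             amp_v = as.vector(amp), phase_rad = as.vector(ph),
             valid = rep(segments$valid, ne))
}

#' Write a measurements table as CSV
#' @param measurements data.frame from \code{\link{measureSegments}}.
#' @param path output CSV path.
#' @export
writeMeasurementsCSV <- function(measurements, path) {
  write.csv(measurements, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
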