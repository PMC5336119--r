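#' @import methods
#' @importFrom stats rnorm runif sd var fft mvfft approx median quantile setNames
#' @importFrom utils read.csv write.csv read.delim write.table head tail
NULL

## Central S4 containers for the EIT pipeline. Conventions:
##  - electrode indices are 1-based everywhere;
##  - voltages in volts, currents in amperes, frequencies in Hz, times in seconds;
##  - "pair" means one (source, sink) current-injection electrode pair;
##  - a "frame" is one full pass through the injection protocol.

#' InjectionProtocol: an ordered set of current-injection electrode pairs
#'
#' @slot pairs integer matrix, one row per injection, columns \code{src}, \code{sink}
#'   (1-based electrode indices).
#' @slot nElectrodes total number of recording electrodes.
#' @slot currentAmplitude injected current in amperes.
#' @slot name free-text label.
#' @export
setClass("InjectionProtocol",
  representation(pairs = "matrix", nElectrodes = "integer",
                 currentAmplitude = "numeric", name = "character"),
  prototype(currentAmplitude = 100e-6, name = ""))

setValidity("InjectionProtocol", function(object) {
  p <- object@pairs
  if (!is.numeric(p) || ncol(p) != 2L || nrow(p) < 1L)
    return("pairs must be a non-empty two-column matrix")
  if (any(p != round(p)) || any(p < 1L) || any(p > object@nElectrodes))
    return("electrode indices must be integers in [1, nElectrodes]")
  if (any(p[, 1L] == p[, 2L]))
    return("source and sink must differ in every pair")
  if (length(object@currentAmplitude) != 1L || object@currentAmplitude <= 0)
    return("currentAmplitude must be a single positive value")
  TRUE
})

#' FrequencyPlan: carrier frequencies with per-frequency durations and currents
#'
#' @slot frequencies carrier frequencies in Hz (ordered as planned).
#' @slot periods number of carrier periods injected per measurement, one per
#'   frequency (injection duration is \code{periods / frequency} seconds).
#' @slot amplitudes injected current per frequency, amperes.
#' @slot ordering one of \code{"fixed"}, \code{"ascending"}, \code{"descending"},
#'   \code{"random"}: the order frequency blocks are visited within each frame.
#' @export
setClass("FrequencyPlan",
  representation(frequencies = "numeric", periods = "numeric",
                 amplitudes = "numeric", ordering = "character"),
  prototype(ordering = "fixed"))

setValidity("FrequencyPlan", function(object) {
  f <- object@frequencies
  if (length(f) < 1L || any(f <= 0)) return("frequencies must be positive")
  if (length(object@periods) != length(f) || any(object@periods < 1))
    return("periods must have one entry >= 1 per frequency")
  if (length(object@amplitudes) != length(f) || any(object@amplitudes <= 0))
    return("amplitudes must have one positive entry per frequency")
  if (!object@ordering %in% c("fixed", "ascending", "descending", "random"))
    return("ordering must be fixed/ascending/descending/random")
  TRUE
})

#' TimingPlan: per-injection durations and gaps
#'
#' When \code{durationS} is \code{NA} the per-injection duration is derived from
#' the frequency plan as \code{periods / frequency}.
#'
#' @slot durationS fixed injection duration in seconds, or \code{NA} to derive
#'   from carrier periods.
#' @slot gapS silent gap between consecutive injections, seconds.
#' @export
setClass("TimingPlan",
  representation(durationS = "numeric", gapS = "numeric"),
  prototype(durationS = NA_real_, gapS = 0))

setValidity("TimingPlan", function(object) {
  if (!is.na(object@durationS) && object@durationS <= 0)
    return("durationS must be positive (or NA to derive from periods)")
  if (object@gapS < 0) return("gapS must be >= 0")
  TRUE
})

#' PhantomModel: transfer impedances of the simulated test object
#'
#' \code{transfer[p, e]} is the signed transfer impedance (ohms) from injection
#' pair \code{p} to single-ended electrode voltage \code{e}; the voltage on
#' electrode e while injecting I amps through pair p is \code{I * transfer[p, e]}
#' (times the dispersion gain at the carrier frequency). A purely resistive
#' phantom is frequency-flat (\code{dispersion} identically 1).
#'
#' @slot transfer numeric matrix pairs x electrodes, ohms (signed).
#' @slot nElectrodes electrode count.
#' @slot dispersion function of frequency (Hz) returning a positive gain on the
#'   baseline transfer impedance; 1 at the model's reference frequency.
#' @export
setClass("PhantomModel",
  representation(transfer = "matrix", nElectrodes = "integer",
                 dispersion = "function"))

setValidity("PhantomModel", function(object) {
  if (ncol(object@transfer) != object@nElectrodes)
    return("transfer must have nElectrodes columns")
  g <- object@dispersion(c(1, 100, 1000))
  if (any(!is.finite(g)) || any(g <= 0))
    return("dispersion gain must be positive and finite")
  TRUE
})

#' NoiseModel: additive white noise and random-walk amplitude drift
#'
#' @slot whiteSd per-sample additive Gaussian noise SD, volts.
#' @slot driftRate random-walk SD on each channel's baseline carrier amplitude,
#'   volts per sqrt(second).
#' @export
setClass("NoiseModel",
  representation(whiteSd = "numeric", driftRate = "numeric"),
  prototype(whiteSd = 0, driftRate = 0))

setValidity("NoiseModel", function(object) {
  if (object@whiteSd < 0 || object@driftRate < 0)
    return("whiteSd and driftRate must be >= 0")
  TRUE
})

#' AmplifierModel: EEG-amplifier front end seen by the carriers
#'
#' @slot samplingRate samples per second.
#' @slot filterType anti-aliasing magnitude model: \code{"first_order"},
#'   \code{"butterworth_n"} or \code{"sinc_power_n"}.
#' @slot cutoffHz anti-aliasing cutoff (-3 dB for the first two types).
#' @slot filterOrder order n for the _n filter types.
#' @slot inputRangeV one-sided input range (container quantisation spans
#'   +/- inputRangeV).
#' @slot resolutionBits ADC resolution used by the file container.
#' @export
setClass("AmplifierModel",
  representation(samplingRate = "numeric", filterType = "character",
                 cutoffHz = "numeric", filterOrder = "numeric",
                 inputRangeV = "numeric", resolutionBits = "numeric"),
  prototype(samplingRate = 16000, filterType = "first_order",
            cutoffHz = 3200, filterOrder = 1, inputRangeV = 0.262,
            resolutionBits = 24))

setValidity("AmplifierModel", function(object) {
  if (object@cutoffHz >= object@samplingRate / 2)
    return("anti-aliasing cutoff must be below Nyquist")
  if (!object@filterType %in% c("first_order", "butterworth_n", "sinc_power_n"))
    return("unknown filterType")
  if (object@inputRangeV <= 0 || object@resolutionBits < 2)
    return("inputRangeV must be positive, resolutionBits >= 2")
  TRUE
})

#' EvokedModel: stimulus-locked fractional impedance transient
#'
#' The transfer impedance on \code{affectedElectrodes} is scaled by
#' \code{1 + dzFraction * pulse(t - tStim)} around each stimulus, where the
#' pulse is a half-sine bump starting \code{latencyS} after the stimulus and
#' lasting \code{durationS} (unit peak). Optionally a low-frequency evoked
#' potential (damped sine, peak \code{epAmplitudeV}) is added to the same
#' electrodes, independent of the carrier.
#'
#' @slot dzFraction fractional impedance change at pulse peak (e.g. 0.001 = 0.1%).
#' @slot latencyS pulse onset after the stimulus, seconds.
#' @slot durationS pulse duration, seconds.
#' @slot affectedElectrodes electrode indices carrying the transient.
#' @slot stimRateHz stimulus repetition rate.
#' @slot nStimuli number of stimuli in the train.
#' @slot epAmplitudeV peak evoked-potential amplitude added at baseband, volts.
#' @export
setClass("EvokedModel",
  representation(dzFraction = "numeric", latencyS = "numeric",
                 durationS = "numeric", affectedElectrodes = "integer",
                 stimRateHz = "numeric", nStimuli = "integer",
                 epAmplitudeV = "numeric"),
  prototype(dzFraction = 0.001, latencyS = 0.007, durationS = 0.011,
            stimRateHz = 2, nStimuli = 60L, epAmplitudeV = 0))

setValidity("EvokedModel", function(object) {
  if (object@durationS <= 0) return("durationS must be positive")
  if (abs(object@dzFraction) >= 1) return("|dzFraction| must be < 1")
  if (object@stimRateHz <= 0 || object@nStimuli < 1L)
    return("stimRateHz must be positive, nStimuli >= 1")
  TRUE
})

#' EventLog: timed controller events recorded on the trigger channel
#'
#' @slot events data.frame with columns \code{sample} (1-based sample index),
#'   \code{code} (event class, see \code{\link{eventCodes}}), \code{payload}
#'   (non-negative integer, e.g. frequency index).
#' @export
setClass("EventLog", representation(events = "data.frame"))

setValidity("EventLog", function(object) {
  ev <- object@events
  need <- c("sample", "code", "payload")
  if (!all(need %in% names(ev))) return("events needs sample/code/payload columns")
  if (nrow(ev) > 0 && is.unsorted(ev$sample)) return("sample indices must be non-decreasing")
  TRUE
})

#' RawRecording: multi-channel sampled voltages plus integer trigger channel
#'
#' @slot data numeric matrix samples x electrodes, volts.
#' @slot triggers integer status-channel samples (same length as rows of data).
#' @slot samplingRate samples per second.
#' @slot channelNames electrode labels.
#' @export
setClass("RawRecording",
  representation(data = "matrix", triggers = "integer",
                 samplingRate = "numeric", channelNames = "character"))

setValidity("RawRecording", function(object) {
  if (length(object@triggers) != nrow(object@data))
    return("trigger channel length must match data rows")
  if (object@samplingRate <= 0) return("samplingRate must be positive")
  TRUE
})

#' BoundaryVoltageFrameSet: demodulated boundary voltages for one frequency
#'
#' The pipeline's central product: demodulated amplitudes (the modulus) and
#' phases for every (frame, injection pair, electrode), with a rejection mask
#' that is uniform across frames (so channel sets are stable over a recording).
#'
#' @slot amplitudes numeric array frames x pairs x electrodes, volts.
#' @slot phases numeric array, same shape, radians.
#' @slot mask logical matrix pairs x electrodes, TRUE = rejected.
#' @slot frequencyHz carrier frequency of this frame block.
#' @slot timestamps frame onset times, seconds.
#' @export
setClass("BoundaryVoltageFrameSet",
  representation(amplitudes = "array", phases = "array", mask = "matrix",
                 frequencyHz = "numeric", timestamps = "numeric"))

setValidity("BoundaryVoltageFrameSet", function(object) {
  d <- dim(object@amplitudes)
  if (length(d) != 3L) return("amplitudes must be frames x pairs x electrodes")
  if (!identical(dim(object@phases), d)) return("phases shape must match amplitudes")
  if (!identical(dim(object@mask), d[2:3])) return("mask must be pairs x electrodes")
  if (any(object@amplitudes < 0, na.rm = TRUE)) return("amplitudes must be >= 0")
  if (length(object@timestamps) != d[1L]) return("one timestamp per frame")
  TRUE
})

#' QCReport: noise, drift, SNR and reciprocity quality metrics
#'
#' @slot channels per-channel table (pair, electrode, mean_v, sd_v, noise_pct,
#'   snr_db).
#' @slot summary named list of summary statistics (each mean +/- SD over
#'   retained channels).
#' @export
setClass("QCReport",
  representation(channels = "data.frame", summary = "list"))

#' TrialSet: stimulus-locked epochs of demodulated amplitude and EEG
#'
#' @slot epochs array trials x channels x time, demodulated amplitude (V).
#' @slot eegEpochs array, same shape, low-passed baseband signal (V).
#' @slot time epoch time axis relative to the stimulus, seconds.
#' @slot baselineS length of pre-stimulus baseline window, seconds.
#' @slot sampleRate samples per second.
#' @slot dropped number of stimuli discarded (incomplete window or flagged).
#' @export
setClass("TrialSet",
  representation(epochs = "array", eegEpochs = "array", time = "numeric",
                 baselineS = "numeric", sampleRate = "numeric",
                 dropped = "integer"))

setValidity("TrialSet", function(object) {
  d <- dim(object@epochs)
  if (length(d) != 3L) return("epochs must be trials x channels x time")
  if (length(object@time) != d[3L]) return("time axis must match epoch length")
  if (object@time[1L] >= 0) return("epoch window must start before the stimulus")
  if (object@baselineS <= 0 || object@baselineS > -object@time[1L])
    return("baseline window must fit in the pre-stimulus part of the epoch")
  TRUE
})

#' EvokedResult: coherently averaged impedance transient
#'
#' @slot dz matrix channels x time: mean change from the pre-stimulus baseline, V.
#' @slot dzPct same, percent of baseline amplitude.
#' @slot sigmaPre per-channel SD of the averaged trace in the baseline window, V.
#' @slot peak per-channel peak |dz| in the search window, V.
#' @slot snr per-channel peak |dz| / sigmaPre.
#' @slot significant per channel, TRUE when peak |dz| > 3 sigmaPre.
#' @slot time epoch time axis, seconds.
#' @slot nTrials trials averaged.
#' @export
setClass("EvokedResult",
  representation(dz = "matrix", dzPct = "matrix", sigmaPre = "numeric",
                 peak = "numeric", snr = "numeric", significant = "logical",
                 time = "numeric", nTrials = "integer"))

#' SpectrumResult: relative impedance change across carrier frequency
#'
#' @slot table data.frame with columns \code{freq_hz}, \code{rel_change_pct}
#'   (vs the reference frequency), \code{se_pct} (standard error over
#'   electrodes), \code{n}.
#' @slot referenceHz the reference frequency (relative change there is 0).
#' @slot orderings the sweep orderings pooled.
#' @export
setClass("SpectrumResult",
  representation(table = "data.frame", referenceHz = "numeric",
                 orderings = "character"))

#' Mesh2D: triangulated 2D domain with boundary electrodes
#'
#' @slot nodes numeric matrix n x 2 of coordinates (m).
#' @slot triangles integer matrix m x 3 of node indices (counter-clockwise).
#' @slot electrodeNodes integer vector: the boundary node carrying each
#'   (point) electrode.
#' @slot conductivity per-element conductivity, S/m.
#' @export
setClass("Mesh2D",
  representation(nodes = "matrix", triangles = "matrix",
                 electrodeNodes = "integer", conductivity = "numeric"))

setValidity("Mesh2D", function(object) {
  if (ncol(object@nodes) != 2L) return("nodes must be n x 2")
  if (ncol(object@triangles) != 3L) return("triangles must be m x 3")
  if (max(object@triangles) > nrow(object@nodes)) return("triangle index out of range")
  if (length(object@conductivity) != nrow(object@triangles))
    return("one conductivity per element")
  if (any(object@conductivity <= 0)) return("conductivity must be positive")
  a <- triangleAreas(object)
  if (any(a <= 0)) return("degenerate or clockwise triangle found")
  if (any(object@electrodeNodes > nrow(object@nodes)))
    return("electrode node index out of range")
  TRUE
})

#' ForwardModel: assembled FEM system with cached factorisation
#'
#' @slot mesh the Mesh2D.
#' @slot stiffness sparse FEM stiffness matrix.
#' @slot groundNode node held at zero potential for solvability.
#' @slot factor cached Cholesky factor of the reduced system.
#' @export
setClass("ForwardModel",
  representation(mesh = "Mesh2D", stiffness = "ANY", groundNode = "integer",
                 factor = "ANY"))

#' ReconResult: Tikhonov-reconstructed conductivity change image
#'
#' @slot deltaSigma per-element conductivity change, S/m.
#' @slot lambda regularisation hyperparameter used.
#' @slot cvCurve data.frame (lambda, cv_error) when lambda was cross-validated.
#' @slot zscores per-element z-scores from the noise-based correction (NA when
#'   no correction was applied).
#' @slot corrected thresholded image after noise-based correction.
#' @export
setClass("ReconResult",
  representation(deltaSigma = "numeric", lambda = "numeric",
                 cvCurve = "data.frame", zscores = "numeric",
                 corrected = "numeric"))
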