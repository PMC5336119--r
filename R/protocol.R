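## Injection protocols, frequency plans and the counting/timing arithmetic of a
## full EIT acquisition.

#' Create an injection protocol
#'
#' @param pairs two-column matrix (or data.frame) of 1-based (source, sink)
#'   electrode indices, one row per injection.
#' @param nElectrodes total number of recording electrodes (default: largest
#'   index used).
#' @param currentAmplitude injected current, amperes.
#' @param name label.
#' @return An \linkS4class{InjectionProtocol}.
#' @examples
#' p <- injectionProtocol(rbind(c(1, 2), c(3, 4)), nElectrodes = 4)
#' countMeasurements(p)
#' @export
injectionProtocol <- function(pairs, nElectrodes = max(pairs),
                              currentAmplitude = 100e-6, name = "") {
  pairs <- as.matrix(pairs)
  storage.mode(pairs) <- "integer"
  colnames(pairs) <- c("src", "sink")
  new("InjectionProtocol", pairs = pairs, nElectrodes = as.integer(nElectrodes),
      currentAmplitude = currentAmplitude, name = name)
}

#' @rdname injectionProtocol
#' @param object,x an InjectionProtocol
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' @rdname injectionProtocol
#' @export
setMethod("nPairs", "InjectionProtocol", function(x) nrow(x@pairs))

#' @rdname injectionProtocol
#' @export
setGeneric("nElectrodes", function(x) standardGeneric("nElectrodes"))

#' @rdname injectionProtocol
#' @export
setMethod("nElectrodes", "InjectionProtocol", function(x) x@nElectrodes)

#' @rdname injectionProtocol
#' @export
setGeneric("protocolPairs", function(x) standardGeneric("protocolPairs"))

#' @rdname injectionProtocol
#' @export
setMethod("protocolPairs", "InjectionProtocol", function(x) x@pairs)

setMethod("show", "InjectionProtocol", function(object) {
  cat(sprintf("InjectionProtocol '%s': %d pairs on %d electrodes, %.3g uA\n",
              object@name, nPairs(object), object@nElectrodes,
              object@currentAmplitude * 1e6))
})

#' Read / write a protocol as CSV (columns src, sink)
#'
#' @param path CSV file with header \code{src,sink}, one injection pair per row.
#' @param ... passed to \code{injectionProtocol}.
#' @return An \linkS4class{InjectionProtocol}.
#' @export
readProtocolCSV <- function(path, ...) {
  tab <- read.csv(path)
  if (!all(c("src", "sink") %in% names(tab)))
    stop("protocol CSV needs columns 'src' and 'sink'")
  injectionProtocol(cbind(tab$src, tab$sink), ...)
}

#' @rdname readProtocolCSV
#' @param protocol an InjectionProtocol to write.
#' @export
writeProtocolCSV <- function(protocol, path) {
  write.csv(as.data.frame(protocol@pairs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Carrier periods per measurement as a function of frequency
#'
#' Banded rules used to keep measurement time roughly constant across a
#' multi-frequency plan: \code{"two_band"} gives 32 periods below 200 Hz and 64
#' at or above; \code{"three_band"} gives 32 below 200 Hz, 64 between 200 Hz and
#' 1 kHz (inclusive), and 128 above 1 kHz.
#'
#' @param f carrier frequency in Hz (vectorised).
#' @param rule "two_band" or "three_band".
#' @return integer periods.
#' @examples
#' periodsForFrequency(100, "two_band")    # 32
#' periodsForFrequency(1700, "three_band") # 128
#' @export
periodsForFrequency <- function(f, rule = c("two_band", "three_band")) {
  rule <- match.arg(rule)
  if (any(f <= 0)) stop("frequency must be positive")
  if (rule == "two_band") {
    ifelse(f < 200, 32L, 64L)
  } else {
    ifelse(f < 200, 32L, ifelse(f <= 1000, 64L, 128L))
  }
}

#' Per-frequency injection current with a low-frequency reduction
#'
#' Implements the current policy as a lookup: a base (safety-limit) amplitude,
#' halved below \code{halveBelowHz} where perception and contact impedance make
#' the full amplitude unusable. Supplied values, not a hard-coded law.
#'
#' @param f frequency in Hz (vectorised).
#' @param baseA base current in amperes.
#' @param halveBelowHz frequencies strictly below this are given half the base.
#' @export
amplitudeForFrequency <- function(f, baseA = 100e-6, halveBelowHz = 200) {
  ifelse(f < halveBelowHz, baseA / 2, baseA)
}

#' Create a frequency plan
#'
#' @param frequencies carrier frequencies, Hz.
#' @param periods periods per injection: either a vector (recycled), or NULL to
#'   apply \code{periodsForFrequency(frequencies, rule)}.
#' @param rule banding rule used when \code{periods} is NULL.
#' @param amplitudes per-frequency current (recycled), amperes.
#' @param ordering frequency-block ordering within each frame.
#' @return A \linkS4class{FrequencyPlan}.
#' @export
frequencyPlan <- function(frequencies, periods = NULL,
                          rule = c("two_band", "three_band"),
                          amplitudes = 100e-6,
                          ordering = c("fixed", "ascending", "descending", "random")) {
  ordering <- match.arg(ordering)
  if (is.null(periods)) periods <- periodsForFrequency(frequencies, match.arg(rule))
  new("FrequencyPlan", frequencies = as.numeric(frequencies),
      periods = rep_len(as.numeric(periods), length(frequencies)),
      amplitudes = rep_len(as.numeric(amplitudes), length(frequencies)),
      ordering = ordering)
}

setMethod("show", "FrequencyPlan", function(object) {
  cat(sprintf("FrequencyPlan: %d frequencies %.4g-%.4g Hz, ordering '%s'\n",
              length(object@frequencies), min(object@frequencies),
              max(object@frequencies), object@ordering))
})

#' Create a timing plan
#'
#' @param durationS fixed per-injection duration in seconds, or NA to derive the
#'   duration of each injection from the frequency plan as periods/frequency
#'   (exact, no rounding to samples at this layer).
#' @param gapS inter-injection gap, seconds.
#' @return A \linkS4class{TimingPlan}.
#' @export
timingPlan <- function(durationS = NA_real_, gapS = 0) {
  new("TimingPlan", durationS = durationS, gapS = gapS)
}

## Per-injection durations (seconds) for one frequency under a timing plan.
injectionDuration <- function(timing, frequencyHz, periods) {
  if (!is.na(timing@durationS)) timing@durationS else periods / frequencyHz
}

#' Duration of one complete protocol frame
#'
#' Sum over all injections (and, in multi-frequency plans, all frequency
#' blocks) of the injection duration plus the inter-injection gap.
#'
#' @param protocol an \linkS4class{InjectionProtocol}.
#' @param timing a \linkS4class{TimingPlan}.
#' @param plan optional \linkS4class{FrequencyPlan}; when given, durations may
#'   be derived per frequency from its periods, and the frame spans all
#'   frequency blocks.
#' @return frame period in seconds.
#' @examples
#' p <- injectionProtocol(cbind(1:34, c(2:34, 1)), nElectrodes = 34)
#' framePeriod(p, timingPlan(0.100))  # 3.4
#' @export
framePeriod <- function(protocol, timing, plan = NULL) {
  np <- nPairs(protocol)
  if (is.null(plan)) {
    if (is.na(timing@durationS))
      stop("a fixed duration or a frequency plan is required")
    per <- timing@durationS + timing@gapS
    return(np * per)
  }
  dur <- mapply(function(f, k) injectionDuration(timing, f, k),
                plan@frequencies, plan@periods)
  sum(np * (dur + timing@gapS))
}

#' Number of voltage measurements per frame
#'
#' Pairs times electrodes when measurements on the injecting electrodes are
#' kept; pairs times (electrodes - 2) when they are excluded.
#'
#' @param protocol an \linkS4class{InjectionProtocol}.
#' @param excludeInjection drop the two injecting electrodes of each pair.
#' @examples
#' p <- injectionProtocol(cbind(1:34, c(2:34, 1)), nElectrodes = 16)
#' @export
countMeasurements <- function(protocol, excludeInjection = FALSE) {
  ne <- nElectrodes(protocol) - if (excludeInjection) 2L else 0L
  nPairs(protocol) * max(ne, 0L)
}

#' Whole frames fitting in a recording of given length
#'
#' @param totalS recording duration, seconds.
#' @param framePeriodS frame period, seconds.
#' @return integer frame count, \code{floor(totalS / framePeriodS)}.
#' @export
framesInDuration <- function(totalS, framePeriodS) {
  if (totalS <= 0 || framePeriodS <= 0) stop("durations must be positive")
  as.integer(floor(totalS / framePeriodS))
}

#' Reciprocal injection/measurement matches in a protocol
#'
#' Two injections a = (i, j) and b = (k, l) form a reciprocal match when their
#' electrode sets are disjoint: the differential voltage measured across (k, l)
#' while injecting through (i, j) has, by reciprocity, the same value as the
#' voltage across (i, j) while injecting through (k, l). Pairs sharing an
#' electrode are skipped because measurements on injecting electrodes are
#' rejected. Matches are unordered-unique (a < b).
#'
#' @param protocol an \linkS4class{InjectionProtocol}.
#' @return data.frame with columns \code{a}, \code{b} (injection indices) and
#'   \code{a_src}, \code{a_sink}, \code{b_src}, \code{b_sink}; zero rows when
#'   the protocol has no reciprocal structure.
#' @export
reciprocalPairs <- function(protocol) {
  p <- protocol@pairs
  n <- nrow(p)
  out <- list()
  if (n >= 2L) {
    for (a in seq_len(n - 1L)) for (b in seq.int(a + 1L, n)) {
      if (length(intersect(p[a, ], p[b, ])) == 0L)
        out[[length(out) + 1L]] <- c(a, b, p[a, ], p[b, ])
    }
  }
  if (length(out) == 0L)
    return(data.frame(a = integer(), b = integer(), a_src = integer(),
                      a_sink = integer(), b_src = integer(), b_sink = integer()))
  m <- do.call(rbind, out)
  data.frame(a = m[, 1], b = m[, 2], a_src = m[, 3], a_sink = m[, 4],
             b_src = m[, 5], b_sink = m[, 6])
}
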