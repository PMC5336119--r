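## Controller trigger semantics: coded pulses marking injection start/stop,
## electrode-pair switching, frequency changes, stimuli and out-of-compliance
## states, encoded on an integer status channel and decoded back into events
## that drive segmentation of the raw recording.

#' Event class codes used on the trigger/status channel
#'
#' Status values are 16-bit: low byte = event class, high byte = payload
#' (e.g. frequency index or stimulus number).
#'
#' @return named integer vector of event-class ids.
#' @export
eventCodes <- function() {
  c(INJ_START = 1L, INJ_STOP = 2L, PAIR_SWITCH = 3L, FREQ_CHANGE = 4L,
    STIM = 5L, OUT_OF_COMPLIANCE = 6L, ZERO_PHASE = 7L)
}

#' Construct an EventLog
#'
#' @param events data.frame with columns \code{sample} (1-based),
#'   \code{code} (event-class name, see \code{\link{eventCodes}}) and optional
#'   \code{payload} (non-negative integer, default 0).
#' @return An \linkS4class{EventLog}.
#' @export
eventLog <- function(events) {
  if (is.null(events$payload)) events$payload <- 0L
  events$sample <- as.integer(events$sample)
  events$payload <- as.integer(events$payload)
  events <- events[order(events$sample), c("sample", "code", "payload")]
  rownames(events) <- NULL
  new("EventLog", events = events)
}

#' @rdname eventLog
#' @param x an EventLog.
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @rdname eventLog
#' @export
setMethod("events", "EventLog", function(x) x@events)

setMethod("show", "EventLog", function(object) {
  ev <- object@events
  cat(sprintf("EventLog: %d events", nrow(ev)))
  if (nrow(ev)) cat(sprintf(" (samples %d..%d)", min(ev$sample), max(ev$sample)))
  cat("\n")
  print(table(ev$code))
})

#' Encode an event log onto an integer status channel
#'
#' Each event is written as the 16-bit value \code{classId + 256 * payload},
#' held for \code{pulseWidth} samples on an otherwise-zero channel.
#'
#' @param log an \linkS4class{EventLog}.
#' @param nSamples channel length.
#' @param pulseWidth pulse width in samples.
#' @param codeMap named integer vector mapping event-class names to ids.
#' @return integer vector of length \code{nSamples}.
#' @export
encodeEvents <- function(log, nSamples, pulseWidth = 4L, codeMap = eventCodes()) {
  ev <- events(log)
  out <- integer(nSamples)
  if (nrow(ev) == 0L) return(out)
  if (any(ev$sample < 1L) || any(ev$sample + pulseWidth - 1L > nSamples))
    stop("event outside recording length")
  if (any(diff(ev$sample) < pulseWidth))
    stop("event collision: two events within one pulse width")
  unknown <- setdiff(ev$code, names(codeMap))
  if (length(unknown)) stop("unknown event code(s): ", paste(unknown, collapse = ", "))
  val <- codeMap[ev$code] + 256L * ev$payload
  for (i in seq_len(nrow(ev)))
    out[ev$sample[i]:(ev$sample[i] + pulseWidth - 1L)] <- val[i]
  out
}

#' Decode a status channel into an event log
#'
#' Rising edges (zero to nonzero, a value change between nonzero levels, or a
#' nonzero level at the first sample) become events; values whose class id is
#' not in the code map are reported with code \code{"UNKNOWN"}.
#'
#' @param status integer status-channel samples.
#' @param codeMap named integer vector of event-class ids.
#' @return An \linkS4class{EventLog}.
#' @export
decodeTriggerChannel <- function(status, codeMap = eventCodes()) {
  status <- as.integer(status)
  prev <- c(0L, status[-length(status)])
  edge <- which(status != 0L & status != prev)
  if (length(edge) == 0L)
    return(eventLog(data.frame(sample = integer(), code = character(),
                               payload = integer())))
  val <- status[edge]
  cls <- val %% 256L
  payload <- val %/% 256L
  names <- names(codeMap)[match(cls, codeMap)]
  names[is.na(names)] <- "UNKNOWN"
  eventLog(data.frame(sample = edge, code = names, payload = payload))
}

#' Segment a recording into per-injection analysis windows
#'
#' Replays the protocol order against the decoded FREQ_CHANGE / PAIR_SWITCH
#' events: a FREQ_CHANGE event opens a frequency block (and is the onset of its
#' first injection), each PAIR_SWITCH the onset of the next injection. Logs
#' without FREQ_CHANGE events are treated as single-frequency with blocks of
#' \code{nPairs} consecutive onsets. Span length is the planned injection
#' duration; the first and last \code{settleFraction} of each span are trimmed
#' from the measurement window to exclude switching transients and filter
#' edges. Spans containing an OUT_OF_COMPLIANCE event are marked invalid.
#'
#' @param recording a \linkS4class{RawRecording}.
#' @param log an \linkS4class{EventLog} (e.g. from
#'   \code{\link{decodeTriggerChannel}}).
#' @param protocol \linkS4class{InjectionProtocol}.
#' @param plan \linkS4class{FrequencyPlan}.
#' @param timing \linkS4class{TimingPlan}.
#' @param settleFraction fraction trimmed at each end of every span.
#' @return data.frame with one row per (frame, frequency block, pair):
#'   \code{frame}, \code{freq_idx}, \code{freq_hz}, \code{pair}, \code{start},
#'   \code{stop} (half-open span), \code{mstart}, \code{mstop} (trimmed
#'   measurement window) and \code{valid}.
#' @export
segmentRecording <- function(recording, log, protocol, plan,
                             timing = timingPlan(), settleFraction = 0.10) {
  fs <- recording@samplingRate
  ev <- events(log)
  np <- nPairs(protocol)
  nf <- length(plan@frequencies)
  onsets <- ev[ev$code %in% c("FREQ_CHANGE", "PAIR_SWITCH"), , drop = FALSE]
  if (nrow(onsets) == 0L) stop("no injection-onset events in log")
  ooc <- ev$sample[ev$code == "OUT_OF_COMPLIANCE"]

  hasFreq <- any(onsets$code == "FREQ_CHANGE")
  rows <- list()
  block <- 0L; posInBlock <- 0L; freqIdx <- 1L
  for (i in seq_len(nrow(onsets))) {
    if (onsets$code[i] == "FREQ_CHANGE" || (!hasFreq && posInBlock %in% c(0L, np))) {
      # new block
      if (block > 0L && posInBlock != np)
        stop(sprintf(
          "event/protocol mismatch: frame %d block %d has %d injections, protocol expects %d",
          ((block - 1L) %/% nf) + 1L, block, posInBlock, np))
      block <- block + 1L
      posInBlock <- 0L
      freqIdx <- if (onsets$code[i] == "FREQ_CHANGE") onsets$payload[i] else 1L
      if (freqIdx < 1L || freqIdx > nf)
        stop("FREQ_CHANGE payload outside the frequency plan")
    }
    posInBlock <- posInBlock + 1L
    if (posInBlock > np)
      stop(sprintf(
        "event/protocol mismatch: frame %d block %d has more than %d injections",
        ((block - 1L) %/% nf) + 1L, block, np))
    f <- plan@frequencies[freqIdx]
    L <- round(injectionDuration(timing, f, plan@periods[freqIdx]) * fs)
    start <- onsets$sample[i]
    stop_ <- start + L
    if (stop_ > nrow(recording@data) + 1L)
      stop("injection span extends past the end of the recording")
    trim <- max(1L, round(settleFraction * L))
    rows[[length(rows) + 1L]] <- data.frame(
      frame = ((block - 1L) %/% nf) + 1L, freq_idx = freqIdx, freq_hz = f,
      pair = posInBlock, start = start, stop = stop_,
      mstart = start + trim, mstop = stop_ - trim,
      valid = !any(ooc >= start & ooc < stop_))
  }
  if (posInBlock != np)
    stop(sprintf(
      "event/protocol mismatch: frame %d block %d has %d injections, protocol expects %d",
      ((block - 1L) %/% nf) + 1L, block, posInBlock, np))
  if (block %% nf != 0L)
    stop(sprintf("event/protocol mismatch: %d frequency blocks do not complete frames of %d",
                 block, nf))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
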