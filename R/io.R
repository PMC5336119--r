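## Raw-recording container: 24-bit-quantised binary sample stream plus a JSON
## sidecar carrying the scaling and layout, and the event log as TSV
## (sample, code, label). Lossless round-trip within one quantisation step.

#' Write a raw recording to disk
#'
#' Writes three files sharing \code{pathBase}: \code{<base>.bin} (sample-major
#' interleaved signed integers: all channels of sample 1, then sample 2, ...;
#' data channels quantised to the amplifier's 24-bit step, trigger channel
#' stored verbatim), \code{<base>.json} (layout, sampling rate, quantisation
#' step, channel names) and \code{<base>.events.tsv} (sample, code, label,
#' payload).
#'
#' @param recording a \linkS4class{RawRecording}.
#' @param log an \linkS4class{EventLog}.
#' @param pathBase path without extension.
#' @param inputRangeV one-sided input range used for quantisation.
#' @param resolutionBits quantisation depth (default 24).
#' @return \code{pathBase}, invisibly.
#' @export
writeRecording <- function(recording, log, pathBase, inputRangeV = 0.262,
                           resolutionBits = 24) {
  step <- 2 * inputRangeV / 2^resolutionBits
  lim <- 2^(resolutionBits - 1) - 1
  q <- round(recording@data / step)
  q[q > lim] <- lim
  q[q < -lim] <- -lim
  storage.mode(q) <- "integer"
  inter <- t(cbind(q, recording@triggers))   # channels x samples -> interleaved
  con <- file(paste0(pathBase, ".bin"), "wb")
  writeBin(as.integer(inter), con, size = 4L, endian = "little")
  close(con)
  meta <- list(n_samples = nrow(recording@data),
               n_channels = ncol(recording@data),
               sampling_rate_hz = recording@samplingRate,
               quantisation_step_v = step,
               input_range_v = inputRangeV,
               resolution_bits = resolutionBits,
               channel_names = recording@channelNames)
  jsonlite::write_json(meta, paste0(pathBase, ".json"), auto_unbox = TRUE,
                       digits = NA)
  writeEventTSV(log, paste0(pathBase, ".events.tsv"))
  invisible(pathBase)
}

#' @rdname writeRecording
#' @export
readRecording <- function(pathBase) {
  meta <- jsonlite::read_json(paste0(pathBase, ".json"), simplifyVector = TRUE)
  nCh <- meta$n_channels
  nS <- meta$n_samples
  con <- file(paste0(pathBase, ".bin"), "rb")
  raw <- readBin(con, "integer", n = (nCh + 1L) * nS, size = 4L,
                 endian = "little")
  close(con)
  if (length(raw) != (nCh + 1L) * nS) stop("malformed recording file: truncated")
  m <- matrix(raw, nrow = nCh + 1L)
  dat <- t(m[seq_len(nCh), , drop = FALSE]) * meta$quantisation_step_v
  trig <- as.integer(m[nCh + 1L, ])
  rec <- new("RawRecording", data = dat, triggers = trig,
             samplingRate = meta$sampling_rate_hz,
             channelNames = as.character(meta$channel_names))
  list(recording = rec, events = readEventTSV(paste0(pathBase, ".events.tsv")))
}

#' Write / read an event log as TSV (sample, code, label, payload)
#'
#' @param log an \linkS4class{EventLog}.
#' @param path TSV file path.
#' @export
writeEventTSV <- function(log, path) {
  ev <- events(log)
  codes <- eventCodes()
  out <- data.frame(sample = ev$sample,
                    code = unname(codes[ev$code] + 256L * ev$payload),
                    label = ev$code, payload = ev$payload)
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeEventTSV
#' @export
readEventTSV <- function(path) {
  tab <- read.delim(path)
  eventLog(data.frame(sample = tab$sample, code = tab$label,
                      payload = tab$payload))
}

setMethod("show", "RawRecording", function(object) {
  cat(sprintf("RawRecording: %d samples x %d channels at %g Hz (%.3f s)\n",
              nrow(object@data), ncol(object@data), object@samplingRate,
              nrow(object@data) / object@samplingRate))
})
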