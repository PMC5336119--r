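## Frame assembly, rejection rules, and the noise / drift / SNR / reciprocity /
## frequency-response quality metrics.

#' Assemble a measurements table into a boundary-voltage frame set
#'
#' @param measurements data.frame from \code{\link{measureSegments}} containing
#'   a single carrier frequency.
#' @param protocol the \linkS4class{InjectionProtocol} that produced it.
#' @param framePeriodS optional frame period used for timestamps.
#' @return a \linkS4class{BoundaryVoltageFrameSet} (nothing rejected yet).
#' @export
assembleFrameSet <- function(measurements, protocol, framePeriodS = 1) {
  f <- unique(measurements$freq_hz)
  if (length(f) != 1L)
    stop("measurements span several frequencies; use assembleMF()")
  nf <- max(measurements$frame)
  np <- nPairs(protocol)
  ne <- nElectrodes(protocol)
  A <- array(NA_real_, c(nf, np, ne))
  P <- array(NA_real_, c(nf, np, ne))
  idx <- cbind(measurements$frame, measurements$pair, measurements$electrode)
  A[idx] <- measurements$amp_v
  P[idx] <- measurements$phase_rad
  if (anyNA(A)) stop("incomplete measurements: missing (frame, pair, electrode) cells")
  mask <- matrix(FALSE, np, ne)
  inval <- idx[!measurements$valid, , drop = FALSE]
  if (nrow(inval)) mask[unique(inval[, 2:3, drop = FALSE])] <- TRUE
  new("BoundaryVoltageFrameSet", amplitudes = A, phases = P, mask = mask,
      frequencyHz = f, timestamps = (seq_len(nf) - 1) * framePeriodS)
}

#' @rdname assembleFrameSet
#' @param x a BoundaryVoltageFrameSet.
#' @export
setGeneric("amplitudes", function(x) standardGeneric("amplitudes"))

#' @rdname assembleFrameSet
#' @export
setMethod("amplitudes", "BoundaryVoltageFrameSet", function(x) x@amplitudes)

#' @rdname assembleFrameSet
#' @export
setGeneric("rejectionMask", function(x) standardGeneric("rejectionMask"))

#' @rdname assembleFrameSet
#' @export
setMethod("rejectionMask", "BoundaryVoltageFrameSet", function(x) x@mask)

#' @rdname assembleFrameSet
#' @export
setGeneric("nRetained", function(x) standardGeneric("nRetained"))

#' @rdname assembleFrameSet
#' @export
setMethod("nRetained", "BoundaryVoltageFrameSet", function(x) sum(!x@mask))

setMethod("show", "BoundaryVoltageFrameSet", function(object) {
  d <- dim(object@amplitudes)
  cat(sprintf(
    "BoundaryVoltageFrameSet: %d frames x %d pairs x %d electrodes at %g Hz; %d/%d channels retained\n",
    d[1], d[2], d[3], object@frequencyHz, sum(!object@mask), d[2] * d[3]))
})

#' Apply measurement rejection rules
#'
#' Marks rejected every (pair, electrode) channel whose mean amplitude across
#' frames falls below \code{minAmplitudeV}, and (optionally) the two injecting
#' electrodes of each pair. The mask is computed from the across-frame mean so
#' the retained channel set is stable over the whole recording.
#'
#' @param frameset a \linkS4class{BoundaryVoltageFrameSet}.
#' @param minAmplitudeV amplitude threshold in volts (>= 0).
#' @param excludeInjection reject measurements on injecting electrodes.
#' @param protocol required when \code{excludeInjection} is TRUE.
#' @return the frame set with an updated rejection mask.
#' @export
applyRejection <- function(frameset, minAmplitudeV = 0,
                           excludeInjection = FALSE, protocol = NULL) {
  stopifnot(minAmplitudeV >= 0)
  meanAmp <- apply(frameset@amplitudes, c(2, 3), mean)
  mask <- frameset@mask | (meanAmp < minAmplitudeV)
  if (excludeInjection) {
    if (is.null(protocol)) stop("protocol needed to exclude injection electrodes")
    p <- protocolPairs(protocol)
    for (i in seq_len(nrow(p))) mask[i, p[i, ]] <- TRUE
  }
  initialize(frameset, mask = mask)
}

channelStats <- function(frameset, frameRange = NULL, capDb = 200) {
  A <- frameset@amplitudes
  if (is.null(frameRange)) frameRange <- seq_len(dim(A)[1L])
  if (length(frameRange) < 2L) stop("need at least two frames")
  keep <- which(!frameset@mask, arr.ind = TRUE)
  rownames(keep) <- NULL
  if (nrow(keep) == 0L) stop("no retained channels")
  mean_v <- sd_v <- numeric(nrow(keep))
  for (i in seq_len(nrow(keep))) {
    x <- A[frameRange, keep[i, 1L], keep[i, 2L]]
    mean_v[i] <- mean(x)
    sd_v[i] <- sd(x)
  }
  noise_pct <- 100 * sd_v / mean_v
  snr_db <- ifelse(sd_v > 0, 20 * log10(mean_v / sd_v), capDb)
  snr_db <- pmin(snr_db, capDb)
  data.frame(pair = keep[, 1L], electrode = keep[, 2L],
             mean_v = mean_v, sd_v = sd_v, noise_pct = noise_pct,
             snr_db = snr_db)
}

#' Noise metrics over a frame range
#'
#' Per retained channel: SD of the demodulated amplitude across frames, the
#' noise as a percentage (100 * SD / mean), and the SNR in dB
#' (20 * log10(mean / SD)); the summary is the mean +/- SD over channels.
#' Channels with zero SD report the capped sentinel of 200 dB.
#'
#' @param frameset a \linkS4class{BoundaryVoltageFrameSet} with rejection applied.
#' @param frameRange frame indices to use (default: all).
#' @return a \linkS4class{QCReport}.
#' @examples
#' # the printed arithmetic: 2.66 mV mean with 0.356 uV SD is 77.5 dB / 0.013%
#' snrDb(2.66e-3, 0.356e-6)
#' @export
noiseMetrics <- function(frameset, frameRange = NULL) {
  ch <- channelStats(frameset, frameRange)
  new("QCReport", channels = ch, summary = list(
    n_channels = nrow(ch),
    mean_v = mean(ch$mean_v), mean_v_sd = sd(ch$mean_v),
    noise_sd_v = mean(ch$sd_v), noise_sd_v_sd = sd(ch$sd_v),
    noise_pct = mean(ch$noise_pct), noise_pct_sd = sd(ch$noise_pct),
    snr_db = mean(ch$snr_db), snr_db_sd = sd(ch$snr_db)))
}

#' SNR / percent-noise arithmetic on a single (mean, SD) pair
#'
#' @param meanV mean demodulated amplitude, volts.
#' @param sdV amplitude SD, volts.
#' @param capDb sentinel for zero SD.
#' @return \code{snrDb}: 20*log10(mean/SD); \code{noisePct}: 100*SD/mean.
#' @export
snrDb <- function(meanV, sdV, capDb = 200) {
  ifelse(sdV > 0, pmin(20 * log10(meanV / sdV), capDb), capDb)
}

#' @rdname snrDb
#' @export
noisePct <- function(meanV, sdV) 100 * sdV / meanV

setMethod("show", "QCReport", function(object) {
  s <- object@summary
  cat("QCReport\n")
  for (k in names(s)) cat(sprintf("  %-14s %s\n", k, format(s[[k]], digits = 6)))
})

#' @rdname noiseMetrics
#' @param x a QCReport.
#' @export
setGeneric("qcSummary", function(x) standardGeneric("qcSummary"))

#' @rdname noiseMetrics
#' @export
setMethod("qcSummary", "QCReport", function(x) x@summary)

#' @rdname noiseMetrics
#' @export
setGeneric("qcChannels", function(x) standardGeneric("qcChannels"))

#' @rdname noiseMetrics
#' @export
setMethod("qcChannels", "QCReport", function(x) x@channels)

#' Voltage drift between the first and last block of frames
#'
#' Per retained channel, the absolute change between the mean amplitude of the
#' last \code{blockSize} frames and that of the first \code{blockSize} frames,
#' also as a percentage of the first-block mean; summarised as mean +/- SD over
#' channels.
#'
#' @param frameset a \linkS4class{BoundaryVoltageFrameSet}.
#' @param blockSize frames per block (default 100).
#' @return list with \code{drift_v}, \code{drift_v_sd}, \code{drift_pct},
#'   \code{drift_pct_sd} and the per-channel table.
#' @export
driftMetric <- function(frameset, blockSize = 100) {
  nf <- dim(frameset@amplitudes)[1L]
  if (nf < 2 * blockSize) {
    if (nf < 4L) stop("too few frames for a drift estimate")
    blockSize <- floor(nf / 2)
  }
  first <- seq_len(blockSize)
  last <- seq.int(nf - blockSize + 1L, nf)
  keep <- which(!frameset@mask, arr.ind = TRUE)
  rownames(keep) <- NULL
  dv <- pct <- numeric(nrow(keep))
  for (i in seq_len(nrow(keep))) {
    x <- frameset@amplitudes[, keep[i, 1L], keep[i, 2L]]
    m0 <- mean(x[first]); m1 <- mean(x[last])
    dv[i] <- abs(m1 - m0)
    pct[i] <- 100 * dv[i] / m0
  }
  list(drift_v = mean(dv), drift_v_sd = sd(dv),
       drift_pct = mean(pct), drift_pct_sd = sd(pct),
       channels = data.frame(pair = keep[, 1L], electrode = keep[, 2L],
                             drift_v = dv, drift_pct = pct))
}

#' Summary SNR per non-overlapping block of frames
#'
#' @param frameset a \linkS4class{BoundaryVoltageFrameSet}.
#' @param blockSize frames per block (>= 2).
#' @return data.frame (block, frame_from, frame_to, snr_db, noise_pct).
#' @export
snrPerBlock <- function(frameset, blockSize = 100) {
  stopifnot(blockSize >= 2)
  nf <- dim(frameset@amplitudes)[1L]
  nb <- nf %/% blockSize
  if (nb < 1L) stop("fewer frames than one block")
  out <- lapply(seq_len(nb), function(b) {
    rng <- ((b - 1L) * blockSize + 1L):(b * blockSize)
    s <- qcSummary(noiseMetrics(frameset, rng))
    data.frame(block = b, frame_from = rng[1L], frame_to = rng[length(rng)],
               snr_db = s$snr_db, noise_pct = s$noise_pct)
  })
  do.call(rbind, out)
}

#' Reciprocity error
#'
#' For every reciprocal match (injections a, b with disjoint electrode sets),
#' compares the differential voltage across b's electrodes while injecting
#' through a with its swapped twin. Signed differential voltages are recovered
#' from (amplitude, phase) as \code{amp * sign(cos(phase))}. The error is
#' \code{100 * |1 - V_small / V_large|} (the larger magnitude in the
#' denominator, making the metric symmetric in a and b), averaged over matches
#' and frames.
#'
#' @param frameset a \linkS4class{BoundaryVoltageFrameSet}.
#' @param protocol the \linkS4class{InjectionProtocol}.
#' @return list with \code{re_pct} (mean), \code{re_pct_sd} and the per-match
#'   table.
#' @export
reciprocityError <- function(frameset, protocol) {
  rp <- reciprocalPairs(protocol)
  if (nrow(rp) == 0L) stop("protocol has no reciprocal matches")
  A <- frameset@amplitudes
  P <- frameset@phases
  nf <- dim(A)[1L]
  signedAmp <- function(fr, pair, e)
    A[fr, pair, e] * sign(cos(P[fr, pair, e]))
  res <- numeric(0)
  tab <- list()
  for (i in seq_len(nrow(rp))) {
    a <- rp$a[i]; b <- rp$b[i]
    for (fr in seq_len(nf)) {
      vab <- signedAmp(fr, a, rp$b_src[i]) - signedAmp(fr, a, rp$b_sink[i])
      vba <- signedAmp(fr, b, rp$a_src[i]) - signedAmp(fr, b, rp$a_sink[i])
      big <- if (abs(vab) >= abs(vba)) vab else vba
      sml <- if (abs(vab) >= abs(vba)) vba else vab
      re <- if (big == 0) NA_real_ else 100 * abs(1 - sml / big)
      res <- c(res, re)
      tab[[length(tab) + 1L]] <- data.frame(a = a, b = b, frame = fr,
                                            v_ab = vab, v_ba = vba, re_pct = re)
    }
  }
  list(re_pct = mean(res, na.rm = TRUE), re_pct_sd = sd(res, na.rm = TRUE),
       matches = do.call(rbind, tab))
}

#' Normalised amplitude versus frequency, and comparison with a filter model
#'
#' Per retained channel, the across-frame mean amplitude at each frequency is
#' expressed as a percentage of the amplitude at the reference frequency; the
#' curve is summarised over channels shared by all frequencies.
#'
#' @param mfList named list of \linkS4class{BoundaryVoltageFrameSet}s, one per
#'   frequency (see \code{\link{assembleMF}}).
#' @param referenceHz reference frequency (must be present).
#' @return data.frame (freq_hz, mean_pct, sd_pct, n).
#' @export
frequencyResponse <- function(mfList, referenceHz) {
  freqs <- unname(vapply(mfList, function(x) x@frequencyHz, numeric(1)))
  ref <- which(abs(freqs - referenceHz) < 1e-9)
  if (length(ref) != 1L) stop("reference frequency not present")
  mask <- Reduce(`|`, lapply(mfList, rejectionMask))
  keep <- which(!mask, arr.ind = TRUE)
  rownames(keep) <- NULL
  if (nrow(keep) == 0L) stop("no channels retained at all frequencies")
  meanAmp <- function(fs) {
    m <- apply(fs@amplitudes, c(2, 3), mean)
    m[keep]
  }
  aRef <- meanAmp(mfList[[ref]])
  out <- lapply(seq_along(mfList), function(i) {
    pct <- 100 * meanAmp(mfList[[i]]) / aRef
    data.frame(freq_hz = freqs[i], mean_pct = mean(pct), sd_pct = sd(pct),
               n = length(pct))
  })
  out <- do.call(rbind, out)
  out[order(out$freq_hz), ]
}

#' @rdname frequencyResponse
#' @param responseTable output of \code{frequencyResponse}.
#' @param amplifier an \linkS4class{AmplifierModel} whose gain curve to compare
#'   against.
#' @return the table with added columns \code{model_pct} (filter-model curve,
#'   normalised at the reference) and \code{error_pct}.
#' @export
compareToFilter <- function(responseTable, amplifier, referenceHz) {
  g <- gainFilter(amplifier, responseTable$freq_hz)
  gRef <- gainFilter(amplifier, referenceHz)
  responseTable$model_pct <- 100 * g / gRef
  responseTable$error_pct <- responseTable$mean_pct - responseTable$model_pct
  responseTable
}

#' Write a QC report as JSON plus human-readable text
#'
#' @param qc a \linkS4class{QCReport}.
#' @param pathBase path without extension; writes <base>.json, <base>.txt and
#'   <base>.channels.csv.
#' @param extra optional named list merged into the JSON (e.g. drift,
#'   reciprocity).
#' @export
writeQCReport <- function(qc, pathBase, extra = list()) {
  s <- c(qcSummary(qc), extra)
  jsonlite::write_json(s, paste0(pathBase, ".json"), auto_unbox = TRUE,
                       digits = NA)
  txt <- c("Quality-control report",
           sprintf("  channels retained : %d", s$n_channels),
           sprintf("  mean amplitude    : %.4g V +/- %.3g", s$mean_v, s$mean_v_sd),
           sprintf("  noise SD          : %.4g V +/- %.3g", s$noise_sd_v, s$noise_sd_v_sd),
           sprintf("  noise             : %.4g %% +/- %.3g", s$noise_pct, s$noise_pct_sd),
           sprintf("  SNR               : %.4g dB +/- %.3g", s$snr_db, s$snr_db_sd))
  if (!is.null(s$drift_pct))
    txt <- c(txt, sprintf("  drift             : %.4g V / %.4g %%", s$drift_v, s$drift_pct))
  if (!is.null(s$re_pct))
    txt <- c(txt, sprintf("  reciprocity error : %.4g %%", s$re_pct))
  writeLines(txt, paste0(pathBase, ".txt"))
  write.csv(qcChannels(qc), paste0(pathBase, ".channels.csv"), row.names = FALSE)
  invisible(pathBase)
}
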