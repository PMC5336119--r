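## Multi-frequency frame handling, frequency-difference datasets and sweep-mode
## impedance-spectrum characterisation.

#' Assemble multi-frequency measurements into per-frequency frame sets
#'
#' Splits a measurements table by carrier frequency, assembles one
#' \linkS4class{BoundaryVoltageFrameSet} per frequency, applies the rejection
#' rule per frequency and then unions the masks so the retained channel set is
#' identical across frequencies.
#'
#' @param measurements data.frame from \code{\link{measureSegments}}.
#' @param protocol the \linkS4class{InjectionProtocol}.
#' @param minAmplitudeV rejection threshold applied per frequency.
#' @param excludeInjection reject measurements on injecting electrodes.
#' @return named list of frame sets (names = frequency in Hz, ascending).
#' @export
assembleMF <- function(measurements, protocol, minAmplitudeV = 0,
                       excludeInjection = FALSE) {
  freqs <- sort(unique(measurements$freq_hz))
  sets <- lapply(freqs, function(f) {
    fsd <- assembleFrameSet(measurements[measurements$freq_hz == f, ], protocol)
    applyRejection(fsd, minAmplitudeV, excludeInjection, protocol)
  })
  shared <- Reduce(`|`, lapply(sets, rejectionMask))
  sets <- lapply(sets, function(s) initialize(s, mask = shared))
  names(sets) <- as.character(freqs)
  sets
}

#' Frequency-difference dataset for imaging
#'
#' Per retained channel, \code{dV = A(f) - A(f0)} of across-frame mean
#' amplitudes, optionally after dividing out the modelled anti-aliasing filter
#' gain so the difference reflects only the load's dispersion.
#'
#' @param mfList output of \code{\link{assembleMF}}.
#' @param referenceHz reference frequency f0.
#' @param amplifier optional \linkS4class{AmplifierModel}; when given, each
#'   frequency's amplitudes are corrected by its gain curve before
#'   differencing.
#' @return data.frame (freq_hz, pair, electrode, dv_v, ref_v).
#' @export
frequencyDifference <- function(mfList, referenceHz, amplifier = NULL) {
  freqs <- unname(vapply(mfList, function(x) x@frequencyHz, numeric(1)))
  ref <- which(abs(freqs - referenceHz) < 1e-9)
  if (length(ref) != 1L) stop("reference frequency not present")
  mask <- rejectionMask(mfList[[ref]])
  keep <- which(!mask, arr.ind = TRUE)
  rownames(keep) <- NULL
  corr <- function(i) {
    m <- apply(mfList[[i]]@amplitudes, c(2, 3), mean)[keep]
    if (!is.null(amplifier)) m <- m / gainFilter(amplifier, freqs[i])
    m
  }
  aRef <- corr(ref)
  out <- lapply(seq_along(mfList), function(i) {
    data.frame(freq_hz = freqs[i], pair = keep[, 1L], electrode = keep[, 2L],
               dv_v = corr(i) - aRef, ref_v = aRef)
  })
  do.call(rbind, out)
}

#' Impedance spectrum from frequency-sweep recordings
#'
#' Pools the demodulated amplitudes of one or more sweep orderings (ascending,
#' descending, random): per frequency the voltages are averaged over electrodes
#' and orderings, then expressed as the relative change (percent) versus the
#' reference frequency. Frequencies missing from some ordering are dropped to
#' the common intersection with a warning.
#'
#' @param sweeps list of measurements tables (one per ordering, see
#'   \code{\link{measureSegments}}), or a single table.
#' @param referenceHz reference frequency; default the lowest common frequency.
#' @param electrodes electrode subset to pool (default all present).
#' @return a \linkS4class{SpectrumResult}.
#' @export
sweepSpectrum <- function(sweeps, referenceHz = NULL, electrodes = NULL) {
  if (is.data.frame(sweeps)) sweeps <- list(sweep = sweeps)
  if (is.null(names(sweeps)))
    names(sweeps) <- paste0("ordering", seq_along(sweeps))
  freqSets <- lapply(sweeps, function(s) sort(unique(s$freq_hz)))
  common <- Reduce(intersect, freqSets)
  if (any(vapply(freqSets, length, 1L) != length(common)))
    warning("orderings cover different frequencies; using the intersection")
  if (length(common) == 0L) stop("no common frequencies across orderings")
  if (is.null(referenceHz)) referenceHz <- min(common)
  if (!any(abs(common - referenceHz) < 1e-9)) stop("reference frequency missing")

  # per (ordering, frequency, electrode) mean amplitude, then pool orderings
  perE <- list()
  for (nm in names(sweeps)) {
    s <- sweeps[[nm]]
    s <- s[s$freq_hz %in% common, ]
    if (!is.null(electrodes)) s <- s[s$electrode %in% electrodes, ]
    agg <- stats::aggregate(amp_v ~ freq_hz + electrode, data = s, FUN = mean)
    agg$ordering <- nm
    perE[[nm]] <- agg
  }
  perE <- do.call(rbind, perE)
  pooled <- stats::aggregate(amp_v ~ freq_hz + electrode, data = perE, FUN = mean)

  refAmp <- pooled$amp_v[abs(pooled$freq_hz - referenceHz) < 1e-9]
  names(refAmp) <- pooled$electrode[abs(pooled$freq_hz - referenceHz) < 1e-9]
  pooled$rel_pct <- 100 * (pooled$amp_v /
                             refAmp[as.character(pooled$electrode)] - 1)
  tab <- do.call(rbind, lapply(split(pooled, pooled$freq_hz), function(g) {
    data.frame(freq_hz = g$freq_hz[1L],
               rel_change_pct = mean(g$rel_pct),
               se_pct = if (nrow(g) > 1L) sd(g$rel_pct) / sqrt(nrow(g)) else 0,
               n = nrow(g))
  }))
  tab <- tab[order(tab$freq_hz), ]
  rownames(tab) <- NULL
  new("SpectrumResult", table = tab, referenceHz = referenceHz,
      orderings = names(sweeps))
}

#' @rdname sweepSpectrum
#' @param x a SpectrumResult.
#' @export
setGeneric("spectrumTable", function(x) standardGeneric("spectrumTable"))

#' @rdname sweepSpectrum
#' @export
setMethod("spectrumTable", "SpectrumResult", function(x) x@table)

setMethod("show", "SpectrumResult", function(object) {
  cat(sprintf("SpectrumResult: %d frequencies, reference %g Hz, orderings: %s\n",
              nrow(object@table), object@referenceHz,
              paste(object@orderings, collapse = ", ")))
})

#' Write a spectrum as CSV (freq_hz, rel_change_pct, se_pct, n)
#' @param spectrum a \linkS4class{SpectrumResult}.
#' @param path output path.
#' @export
writeSpectrumCSV <- function(spectrum, path) {
  write.csv(spectrumTable(spectrum), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
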