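## Packaged synthetic fixtures: injection protocols used by the characterisation
## designs and a constructed resistive phantom transfer table.

#' Packaged injection protocols
#'
#' \code{"head16"}: 34 injection pairs on 16 electrodes (the scalp-recording
#' style protocol of the phantom characterisation design, 544 measurements per
#' frame). \code{"scalp32"}: 31 pairs on 32 electrodes (930 measurements per
#' frame when the injecting electrodes are excluded).
#'
#' @param name protocol name.
#' @param currentAmplitude injected current, amperes.
#' @return an \linkS4class{InjectionProtocol}.
#' @export
protocolFixture <- function(name = c("head16", "scalp32"),
                            currentAmplitude = 100e-6) {
  name <- match.arg(name)
  file <- c(head16 = "protocol_34x16.csv", scalp32 = "protocol_31x32.csv")[name]
  ne <- c(head16 = 16L, scalp32 = 32L)[name]
  path <- system.file("extdata", file, package = "eitproc", mustWork = TRUE)
  readProtocolCSV(path, nElectrodes = ne, currentAmplitude = currentAmplitude,
                  name = name)
}

#' Packaged synthetic resistive phantom
#'
#' A constructed (synthetic) transfer-impedance table for the 34-pair /
#' 16-electrode protocol, derived from the package's 2D FEM disc forward model
#' and rescaled so that, at 100 uA injection at 2 kHz through the default
#' EEG-amplifier front end (first-order anti-aliasing at 3.2 kHz, gain 0.848)
#' with the 250 uV rejection threshold and injection-electrode exclusion,
#' exactly 363 of the 544 channels are retained and the retained channels have
#' a geometric-mean boundary voltage of 2.66 mV. The rescaling is monotone in amplitude; it preserves the
#' FEM solution's channel ordering and signs but only approximately its exact
#' reciprocity (use \code{\link{femPhantom}} directly where exact reciprocity
#' matters).
#'
#' A companion \code{"scalp32"} table (31 pairs x 32 electrodes, for the
#' 160 uA / 1 mV-threshold design) is constructed the same way with a single
#' global scale placing 540 of its 930 non-injection channels above threshold;
#' being a pure scaling of the FEM solution it keeps exact reciprocity.
#'
#' @param name \code{"head16"} (34 x 16) or \code{"scalp32"} (31 x 32).
#' @param dispersion gain function of frequency (default: purely resistive).
#' @return a \linkS4class{PhantomModel}.
#' @export
phantomFixture <- function(name = c("head16", "scalp32"),
                           dispersion = function(f) rep(1, length(f))) {
  name <- match.arg(name)
  file <- c(head16 = "phantom_transfer_synthetic.csv",
            scalp32 = "scalp_transfer_synthetic.csv")[name]
  path <- system.file("extdata", file, package = "eitproc", mustWork = TRUE)
  tab <- read.csv(path)
  np <- max(tab$pair); ne <- max(tab$electrode)
  tr <- matrix(NA_real_, np, ne)
  tr[cbind(tab$pair, tab$electrode)] <- tab$z_ohm
  phantomModel(tr, dispersion)
}

#' Read / write a transfer table CSV (pair, electrode, z_ohm)
#' @param path CSV path.
#' @export
readTransferCSV <- function(path) {
  tab <- read.csv(path)
  tr <- matrix(NA_real_, max(tab$pair), max(tab$electrode))
  tr[cbind(tab$pair, tab$electrode)] <- tab$z_ohm
  tr
}

#' @rdname readTransferCSV
#' @param transfer pairs x electrodes matrix, ohms.
#' @export
writeTransferCSV <- function(transfer, path) {
  idx <- expand.grid(pair = seq_len(nrow(transfer)),
                     electrode = seq_len(ncol(transfer)))
  write.csv(data.frame(idx, z_ohm = transfer[as.matrix(idx)]), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}
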