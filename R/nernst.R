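#' Build a safranine-O membrane-potential calibration
#'
#' Collects every constant of the Nernst conversion. The mitochondrial volume
#' is taken as 3.1 uL per mg of tissue. \code{cFCCP}, the extramitochondrial
#' safranine concentration after full uncoupling, may be left \code{NA} and
#' estimated from the FCCP state of a recording by
#' \code{\link{analyzeOxygraph}}; the difference \code{cTotal - cFCCP} is the
#' non-mitochondrial uptake that the conversion subtracts.
#'
#' @param tissueMass_mg tissue mass in the chamber, mg.
#' @param cTotal_uM total safranine-O added, uM.
#' @param cFCCP_uM safranine signal after FCCP, uM (NA = estimate later).
#' @param vRB_ml respiration-buffer volume, mL.
#' @param vMitoPerMg_ul mitochondrial volume per mg tissue, uL/mg.
#' @param temperature_K assay temperature (default 310.15 K = 37 C).
#' @return A \linkS4class{PsiCalibration}.
#' @export
psiCalibration <- function(tissueMass_mg, cTotal_uM = 2, cFCCP_uM = NA_real_,
                           vRB_ml = 2, vMitoPerMg_ul = 3.1,
                           temperature_K = 310.15) {
  new("PsiCalibration", cTotal = cTotal_uM, cFCCP = cFCCP_uM, vRB = vRB_ml,
      vMito = vMitoPerMg_ul * tissueMass_mg, temperature = temperature_K,
      z = 1, gasConstant = 8.314, faraday = 96485)
}

# RT/zF in mV for a calibration.
nernstSlope <- function(calib) {
  1000 * calib@gasConstant * calib@temperature / (calib@z * calib@faraday)
}

#' Convert extramitochondrial safranine-O concentration to membrane potential
#'
#' The lipophilic cation safranine-O partitions into energized mitochondria
#' according to the membrane potential. With \code{C_out = C_RB} (the
#' concentration remaining in the buffer) and the matrix concentration
#' reconstructed by mass balance,
#' \code{C_in = (C_FCCP - C_RB) * V_RB / V_mito} (volumes in the same units),
#' the potential is \code{psi = (RT/zF) ln(C_out/C_in)}, returned in mV.
#' Energized mitochondria give negative potentials.
#'
#' @param cRB safranine-O concentration in the buffer, uM (vectorised).
#' @param calib a \linkS4class{PsiCalibration} with finite \code{cFCCP}.
#' @return Membrane potential(s), mV.
#' @export
safranineToPsi <- function(cRB, calib) {
  stopifnot(is(calib, "PsiCalibration"))
  if (!is.finite(calib@cFCCP))
    cfStop("calibration cFCCP is NA: supply it or estimate from an FCCP state",
           "cardioflux_psi_error")
  if (any(cRB <= 0)) cfStop("cRB must be > 0", "cardioflux_psi_error")
  if (any(cRB >= calib@cFCCP))
    cfStop("no net mitochondrial safranine uptake (cRB >= cFCCP)",
           "cardioflux_psi_error")
  cOut <- cRB
  cIn <- (calib@cFCCP - cRB) * (calib@vRB * 1000) / calib@vMito
  nernstSlope(calib) * log(cOut / cIn)
}

#' Invert the Nernst conversion: membrane potential to buffer concentration
#'
#' Closed-form inverse of \code{\link{safranineToPsi}}; used by the synthetic
#' oxygraph generator to construct safranine signals with a known
#' ground-truth potential. Monotone: stronger (more negative) potentials give
#' lower buffer concentrations.
#'
#' @param psi membrane potential(s), mV; must be <= 0.
#' @param calib a \linkS4class{PsiCalibration} with finite \code{cFCCP}.
#' @return Buffer safranine-O concentration(s) \code{cRB}, uM.
#' @export
inversePsi <- function(psi, calib) {
  stopifnot(is(calib, "PsiCalibration"))
  if (any(psi > 0)) cfStop("psi must be <= 0", "cardioflux_psi_error")
  if (!is.finite(calib@cFCCP))
    cfStop("calibration cFCCP is NA", "cardioflux_psi_error")
  r <- (calib@vRB * 1000) / calib@vMito
  rho <- exp(psi / nernstSlope(calib))   # C_out/C_in
  calib@cFCCP * rho * r / (1 + rho * r)
}

#' Two-point linear calibration of a raw safranine fluorescence channel
#'
#' Maps raw fluorescence to concentration (uM) assuming linearity between the
#' zero-signal reading and the reading at the known total added
#' concentration.
#'
#' @param raw raw fluorescence values.
#' @param zero_signal raw reading at 0 uM.
#' @param total_signal raw reading at \code{cTotal_uM}.
#' @param cTotal_uM the known added concentration (2 uM in the assay).
#' @return Calibrated concentrations, uM.
#' @export
safranineCalibrate <- function(raw, zero_signal, total_signal, cTotal_uM = 2) {
  if (total_signal == zero_signal)
    cfStop("degenerate safranine calibration (equal anchor signals)",
           "cardioflux_psi_error")
  (raw - zero_signal) / (total_signal - zero_signal) * cTotal_uM
}
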