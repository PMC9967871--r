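#' Default respiratory-state protocol for the synthetic oxygraph generator
#'
#' One row per addition, in protocol order: complex-I substrates (GMP, Leak
#' state), ADP + hexokinase/glucose (OXPHOS), a CaCl2 bolus, and FCCP.
#' O2 slopes are in uM/s (negative = consumption); \code{psi} is the target
#' membrane potential in mV (\code{NA} for the FCCP state, which sits at the
#' uncoupled safranine level by definition).
#'
#' @param leak_psi,oxphos_psi,ca_psi state potentials, mV.
#' @return data.frame with columns \code{label}, \code{duration},
#'   \code{o2_slope}, \code{psi}, \code{dose}.
#' @export
oxygraphProtocol <- function(leak_psi = -210, oxphos_psi = -170,
                             ca_psi = -160) {
  data.frame(
    label = c("GMP", "ADP_HEX", "CACL2", "FCCP"),
    duration = c(300, 300, 300, 180),
    o2_slope = c(-0.01, -0.04, -0.045, -0.05),
    psi = c(leak_psi, oxphos_psi, ca_psi, NA_real_),
    dose = c(NA_real_, NA_real_, 0.3, NA_real_),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic oxygraph recording with known per-state ground truth
#'
#' O2 concentration is piecewise linear (continuous across states) with the
#' configured slope per state; the safranine channel is constant per state at
#' \code{inversePsi(psi)} for energized states and at the calibration's
#' \code{cFCCP} for the FCCP state, plus optional Gaussian noise. Event
#' markers are emitted at the state boundaries.
#'
#' @param protocol data.frame as from \code{\link{oxygraphProtocol}}.
#' @param calib a \linkS4class{PsiCalibration} with finite \code{cFCCP}.
#' @param o2_start initial O2 concentration, uM.
#' @param noise_sd length-2 (or named) vector: Gaussian noise SD for the o2
#'   and safranine channels.
#' @param sampling_rate Hz (oxygraph channels are slow; default 1 Hz).
#' @param freeCaLadder ladder passed through to the recording.
#' @param tissue_mass chamber tissue mass, mg; defaults to the mass implied
#'   by the calibration's mitochondrial volume at 3.1 uL/mg.
#' @param seed mandatory RNG seed.
#' @return An \linkS4class{OxygraphRecording}; attribute \code{ground_truth}
#'   holds per-state flux (pmol s^-1 mg^-1), psi (mV) and the protocol.
#' @export
genOxygraph <- function(protocol = oxygraphProtocol(), calib,
                        o2_start = 200, noise_sd = c(o2 = 0, safranine = 0),
                        sampling_rate = 1, freeCaLadder = NULL,
                        tissue_mass = NULL, seed) {
  stopifnot(is(calib, "PsiCalibration"))
  if (!is.finite(calib@cFCCP))
    cfStop("generator needs a calibration with finite cFCCP",
           "cardioflux_gen_error")
  en <- protocol$label != "FCCP"
  if (any(is.finite(protocol$psi[en]) & protocol$psi[en] > 0))
    cfStop("energized states must have psi <= 0", "cardioflux_gen_error")
  dt <- 1 / sampling_rate
  starts <- cumsum(c(0, protocol$duration[-nrow(protocol)]))
  total <- sum(protocol$duration)
  t <- seq(0, total - dt, by = dt)
  state_of <- findInterval(t, starts)
  o2 <- numeric(length(t))
  saf <- numeric(length(t))
  o2_at_start <- o2_start
  for (i in seq_len(nrow(protocol))) {
    sel <- state_of == i
    o2[sel] <- o2_at_start + protocol$o2_slope[i] * (t[sel] - starts[i])
    o2_at_start <- o2_at_start + protocol$o2_slope[i] * protocol$duration[i]
    saf[sel] <- if (protocol$label[i] == "FCCP") calib@cFCCP else
      inversePsi(protocol$psi[i], calib)
  }
  if (any(o2 < 0))
    cfStop("protocol drives O2 below zero: shorten states or raise o2_start",
           "cardioflux_gen_error")
  nsd <- if (!is.null(names(noise_sd))) noise_sd else
    stats::setNames(rep_len(noise_sd, 2L), c("o2", "safranine"))
  mass <- if (is.null(tissue_mass)) calib@vMito / 3.1 else tissue_mass
  withSeed(seed, {
    if (nsd[["o2"]] > 0) o2 <- pmax(o2 + nsd[["o2"]] * stats::rnorm(length(t)), 0)
    if (nsd[["safranine"]] > 0)
      saf <- saf + nsd[["safranine"]] * stats::rnorm(length(t))
    rec <- OxygraphRecording(
      t, o2, saf,
      events = data.frame(label = protocol$label, time = starts,
                          dose = protocol$dose, stringsAsFactors = FALSE),
      chamberVolume = calib@vRB, tissueMass = mass,
      freeCaLadder = freeCaLadder)
    attr(rec, "ground_truth") <- list(
      protocol = protocol,
      flux = -protocol$o2_slope * calib@vRB * 1000 / mass,
      psi = ifelse(protocol$label == "FCCP", 0, protocol$psi),
      seed = seed)
    rec
  })
}
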