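# Respiratory-state segmentation, O2 flux and per-state membrane potential.

.stateLabels <- function(events) {
  labs <- character(nrow(events))
  k <- 0L
  for (i in seq_len(nrow(events))) {
    labs[i] <- switch(events$label[i],
                      GMP = "CI_Leak", ADP_HEX = "CI_OXPHOS",
                      CACL2 = { k <- k + 1L; sprintf("Ca_titration_%d", k) },
                      FCCP = "FCCP")
  }
  labs
}

#' Segment an oxygraph recording into respiratory states
#'
#' Each titration event opens a state window that starts \code{settle}
#' seconds after the addition (mixing/stabilisation) and ends at the next
#' event (the last runs to the end of the recording). A state is flagged
#' \code{steady} when the O2 flux drifts by less than \code{steady_tol} per
#' second over the last third of its window (quadratic fit to the O2 trace;
#' the second-derivative term is the flux drift).
#'
#' @param rec an \linkS4class{OxygraphRecording}; must contain a GMP event.
#' @param settle seconds discarded after each addition (default 60).
#' @param steady_tol flux-drift tolerance, pmol s^-1 mg^-1 per s.
#' @return data.frame: \code{state}, \code{label} (event label),
#'   \code{t_start}, \code{t_end}, \code{event_time}, \code{dose},
#'   \code{steady}.
#' @export
segmentStates <- function(rec, settle = 60, steady_tol = 0.05) {
  stopifnot(is(rec, "OxygraphRecording"))
  ev <- rec@events
  if (!"GMP" %in% ev$label)
    cfStop("missing GMP event: recording has no energized baseline state",
           "cardioflux_oxygraph_error")
  t_end_rec <- rec@time[length(rec@time)]
  starts <- ev$time + settle
  ends <- c(ev$time[-1L], t_end_rec)
  labs <- .stateLabels(ev)
  for (i in seq_along(starts))
    if (starts[i] >= ends[i])
      cfStop(sprintf("settle time leaves an empty window for state %s", labs[i]),
             "cardioflux_oxygraph_error")
  steady <- logical(length(starts))
  for (i in seq_along(starts)) {
    tail_sel <- which(rec@time >= ends[i] - (ends[i] - starts[i]) / 3 &
                        rec@time < ends[i])
    if (length(tail_sel) >= 5L) {
      tt <- rec@time[tail_sel] - rec@time[tail_sel[1]]
      q <- stats::coef(stats::lm(rec@o2[tail_sel] ~ tt + I(tt^2)))
      drift <- abs(2 * q[3]) * rec@chamberVolume * 1000 / rec@tissueMass
      steady[i] <- is.finite(drift) && drift < steady_tol
    }
  }
  data.frame(state = seq_along(starts), label = labs, t_start = starts,
             t_end = ends, event_time = ev$time, dose = ev$dose,
             steady = steady, stringsAsFactors = FALSE)
}

#' Mass-specific oxygen flux over a window
#'
#' Least-squares slope of the O2 concentration over the window, converted to
#' a mass-specific molar flux:
#' \code{flux = -slope [uM/s] x chamber volume [mL] x 1000 / mass [mg]}
#' in pmol s^-1 mg^-1. A positive O2 slope beyond \code{increase_tol} (O2
#' rising, i.e. a leaky chamber or calibration drift) is flagged via the
#' \code{"o2_increasing"} attribute but the flux is still returned.
#'
#' @param rec an \linkS4class{OxygraphRecording}.
#' @param window list/row with \code{t_start}, \code{t_end} (s).
#' @param mass tissue mass, mg; defaults to the recording's.
#' @param increase_tol uM/s.
#' @return Flux in pmol s^-1 mg^-1 (attribute \code{o2_increasing} logical).
#' @export
computeFlux <- function(rec, window, mass = NULL, increase_tol = 1e-3) {
  stopifnot(is(rec, "OxygraphRecording"))
  if (is.null(mass)) mass <- rec@tissueMass
  sel <- which(inWindow(rec@time, window$t_start, window$t_end))
  if (length(sel) < 10L)
    cfStop("flux window must contain at least 10 samples",
           "cardioflux_oxygraph_error")
  slope <- stats::coef(stats::lm(rec@o2[sel] ~ rec@time[sel]))[2]
  flux <- -slope * rec@chamberVolume * 1000 / mass
  structure(unname(flux), o2_increasing = unname(slope > increase_tol))
}

# Map a cumulative CaCl2 dose to free calcium via the supplied ladder.
.freeCaFromLadder <- function(ladder, cumulative_mM) {
  if (is.null(ladder) || !nrow(ladder) || !is.finite(cumulative_mM))
    return(NA_real_)
  hit <- which(abs(ladder$cacl2_mM - cumulative_mM) < 1e-6)
  if (length(hit)) ladder$free_ca_uM[hit[1]] else NA_real_
}

#' Per-state oxygen flux and membrane potential
#'
#' Composition of \code{\link{segmentStates}}, \code{\link{computeFlux}} and
#' \code{\link{safranineToPsi}}. Per-state readouts are taken over the steady
#' tail (the last third of each state window): the flux from the O2 slope
#' there, the potential from the mean safranine concentration there. The FCCP
#' state is depolarised by definition (psi = 0); it also supplies the
#' \code{cFCCP} estimate when the calibration has none. Calcium-titration
#' states are annotated with free calcium from the recording's ladder
#' (cumulative dose; \code{NA} when the ladder is missing). States where the
#' buffer concentration shows no net mitochondrial uptake get \code{psi = NA}.
#'
#' @param rec an \linkS4class{OxygraphRecording}.
#' @param calib a \linkS4class{PsiCalibration}; if its \code{cFCCP} is NA it
#'   is estimated from the FCCP-state steady tail.
#' @param settle,steady_tol passed to \code{\link{segmentStates}}.
#' @return data.frame: \code{state}, \code{label}, \code{t_start},
#'   \code{t_end}, \code{flux} (pmol s^-1 mg^-1), \code{psi} (mV),
#'   \code{free_ca} (uM), \code{steady}.
#' @export
analyzeOxygraph <- function(rec, calib, settle = 60, steady_tol = 0.05) {
  states <- segmentStates(rec, settle, steady_tol)
  tails <- lapply(seq_len(nrow(states)), function(i) {
    w <- states[i, ]
    list(t_start = w$t_end - (w$t_end - w$t_start) / 3, t_end = w$t_end)
  })
  if (!is.finite(calib@cFCCP)) {
    ifccp <- which(states$label == "FCCP")
    if (!length(ifccp))
      cfStop("calibration cFCCP is NA and the recording has no FCCP state",
             "cardioflux_psi_error")
    sel <- inWindow(rec@time, tails[[ifccp]]$t_start, tails[[ifccp]]$t_end)
    calib@cFCCP <- mean(rec@safranine[sel])
  }
  cum_dose <- 0
  out <- states[c("state", "label", "t_start", "t_end", "steady")]
  out$flux <- NA_real_; out$psi <- NA_real_; out$free_ca <- NA_real_
  for (i in seq_len(nrow(states))) {
    out$flux[i] <- computeFlux(rec, tails[[i]])
    if (states$label[i] == "FCCP") {
      out$psi[i] <- 0
    } else {
      sel <- inWindow(rec@time, tails[[i]]$t_start, tails[[i]]$t_end)
      cRB <- mean(rec@safranine[sel])
      out$psi[i] <- if (cRB > 0 && cRB < calib@cFCCP)
        safranineToPsi(cRB, calib) else NA_real_
    }
    if (startsWith(states$label[i], "Ca_titration")) {
      cum_dose <- cum_dose + if (is.finite(states$dose[i])) states$dose[i] else NA_real_
      out$free_ca[i] <- .freeCaFromLadder(rec@freeCaLadder, cum_dose)
    }
  }
  out[c("state", "label", "t_start", "t_end", "flux", "psi", "free_ca", "steady")]
}

#' Detect mPTP opening during calcium titration
#'
#' Opening of the permeability transition pore depolarises the membrane
#' irreversibly: the safranine signal rises back toward its uncoupled level.
#' Detection only: flags a sustained safranine rise (slope above
#' \code{slope_tol} over a calcium-titration state) that reaches at least
#' \code{frac_fccp} of the FCCP level.
#'
#' @param rec an \linkS4class{OxygraphRecording}.
#' @param calib a \linkS4class{PsiCalibration} (finite \code{cFCCP}).
#' @param slope_tol uM/s safranine rise considered sustained.
#' @param frac_fccp fraction of \code{cFCCP} that must be reached.
#' @param settle as in \code{\link{segmentStates}}.
#' @return A list: \code{opened} (logical), \code{time} (s or NA).
#' @export
detectMptp <- function(rec, calib, slope_tol = 5e-4, frac_fccp = 0.8,
                       settle = 60) {
  states <- segmentStates(rec, settle)
  ca <- states[startsWith(states$label, "Ca_titration"), , drop = FALSE]
  for (i in seq_len(nrow(ca))) {
    sel <- which(inWindow(rec@time, ca$t_start[i], ca$t_end[i]))
    if (length(sel) < 10L) next
    slope <- stats::coef(stats::lm(rec@safranine[sel] ~ rec@time[sel]))[2]
    reached <- rec@safranine[sel] >= frac_fccp * calib@cFCCP
    if (slope > slope_tol && any(reached))
      return(list(opened = TRUE, time = rec@time[sel[which(reached)[1]]]))
  }
  list(opened = FALSE, time = NA_real_)
}
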