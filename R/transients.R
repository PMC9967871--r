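#' Analysis configuration for per-beat transient quantification
#'
#' All tunables of \code{\link{analyzeTransient}} in one list, pinned to the
#' package defaults: 50 ms pre-upstroke baseline for the diastolic level, a
#' 5-sample moving average (12.5 ms at 400 Hz) before peak/derivative
#' extraction, a noise floor of 3 baseline SDs for beat acceptance, and a
#' decay fit starting at the peak sample.
#'
#' @param baseline_ms pre-upstroke baseline segment, ms (diastolic = its mean).
#' @param smooth_width moving-average width in samples applied before peak
#'   and derivative extraction (1 = off).
#' @param noise_k beats with amplitude below \code{noise_k} x baseline SD are
#'   rejected.
#' @param decay_start \code{"peak"} (default) or \code{"p90"} (first sample
#'   after the peak at or below 90\% of the amplitude).
#' @param decay_delay_s extra delay d after the decay start before the fit
#'   window begins.
#' @param ttp_reference \code{"stimulus"} (default) or \code{"onset"}: the
#'   time-to-peak origin. Onset is the first sample exceeding diastolic +
#'   \code{noise_k} x baseline SD.
#' @param peak_estimate \code{"fit"} (default): the peak value is the fitted
#'   decay extrapolated to the peak time (A + C at the fit start), which is
#'   exact on noiseless data and free of the upward max-of-noise selection
#'   bias; \code{"smoothed_max"}: the maximum of the smoothed signal. The
#'   peak location (time-to-peak) always comes from the smoothed maximum,
#'   and \code{"fit"} falls back to the smoothed maximum when the decay fit
#'   fails.
#' @return A named list of class \code{cardioflux_config}.
#' @export
transientConfig <- function(baseline_ms = 50, smooth_width = 5L, noise_k = 3,
                            decay_start = c("peak", "p90"),
                            decay_delay_s = 0,
                            ttp_reference = c("stimulus", "onset"),
                            peak_estimate = c("fit", "smoothed_max")) {
  structure(list(baseline_ms = baseline_ms,
                 smooth_width = as.integer(smooth_width),
                 noise_k = noise_k, decay_start = match.arg(decay_start),
                 decay_delay_s = decay_delay_s,
                 ttp_reference = match.arg(ttp_reference),
                 peak_estimate = match.arg(peak_estimate)),
            class = "cardioflux_config")
}

#' Segment a paced recording into beat windows
#'
#' One half-open window \code{[stim, stim + 1/f)} per stimulus; a partial
#' final window is dropped. Explicit stimulus times override the frequency;
#' their windows extend to the next stimulus (the last one gets the median
#' inter-stimulus interval).
#'
#' @param x a \linkS4class{RatioTrace}.
#' @param stim_freq pacing frequency, Hz; defaults to the trace's.
#' @param stim_times optional explicit stimulus times (s).
#' @return data.frame with columns \code{beat}, \code{stim_time},
#'   \code{t_start}, \code{t_end}.
#' @export
segmentBeats <- function(x, stim_freq = NULL, stim_times = NULL) {
  stopifnot(is(x, "RatioTrace"))
  t0 <- x@time[1]; t_end <- x@time[length(x@time)]
  dt <- stats::median(diff(x@time))
  if (is.null(stim_times) && length(x@stimTimes)) stim_times <- x@stimTimes
  if (is.null(stim_freq)) stim_freq <- x@stimFreq
  if (is.null(stim_times)) {
    if (!is.numeric(stim_freq) || stim_freq <= 0)
      cfStop("need stim_freq > 0 or explicit stim_times", "cardioflux_segment_error")
    period <- 1 / stim_freq
    stim <- seq(t0, t_end, by = period)
    ends <- stim + period
  } else {
    stim <- sort(stim_times)
    period <- if (length(stim) > 1L) stats::median(diff(stim)) else
      if (stim_freq > 0) 1 / stim_freq else
        cfStop("single stimulus time needs stim_freq for the window width",
               "cardioflux_segment_error")
    ends <- c(stim[-1L], stim[length(stim)] + period)
  }
  keep <- ends <= t_end + dt / 2
  if (!any(keep))
    cfStop("zero usable beat windows in recording", "cardioflux_segment_error")
  data.frame(beat = seq_len(sum(keep)), stim_time = stim[keep],
             t_start = stim[keep], t_end = ends[keep])
}

#' Extract kinetic parameters from one transient
#'
#' The per-beat quintet: diastolic level (mean over the pre-upstroke
#' baseline), amplitude (peak - diastolic), maximum rate of rise (max of the
#' smoothed central-difference derivative between stimulus and peak, in
#' signal units per ms), time-to-peak (stimulus to peak, s) and the decay
#' time constant tau from a least-squares monoexponential fit with free
#' offset over [peak (+ delay), window end). Peak location is the earliest
#' maximum of the smoothed signal (deterministic tie-break).
#'
#' Beats whose amplitude does not exceed \code{noise_k} x baseline SD are
#' returned with \code{accepted = FALSE} and reason "amplitude below noise
#' floor"; a non-convergent decay fit keeps the beat but marks \code{tau_decay}
#' \code{NA} with the failure reason.
#'
#' @param x a \linkS4class{RatioTrace}.
#' @param window one row of \code{\link{segmentBeats}} output (or a list with
#'   \code{stim_time}, \code{t_start}, \code{t_end}, optionally \code{beat}).
#' @param config see \code{\link{transientConfig}}.
#' @return One-row data.frame: \code{beat}, \code{diastolic}, \code{peak},
#'   \code{amplitude}, \code{max_rate_of_rise} (per ms), \code{time_to_peak}
#'   (s), \code{tau_decay} (s), \code{fit_rmse}, \code{fit_r2},
#'   \code{accepted}, \code{reject_reason}.
#' @export
analyzeTransient <- function(x, window, config = transientConfig()) {
  stopifnot(is(x, "RatioTrace"))
  sel <- inWindow(x@time, window$t_start, window$t_end)
  if (sum(sel) < 20L)
    cfStop("beat window must contain at least 20 samples", "cardioflux_segment_error")
  t <- x@time[sel]; y <- x@signal[sel]
  dt <- stats::median(diff(t))
  out <- data.frame(beat = if (!is.null(window$beat)) window$beat else NA_integer_,
                    diastolic = NA_real_, peak = NA_real_, amplitude = NA_real_,
                    max_rate_of_rise = NA_real_, time_to_peak = NA_real_,
                    tau_decay = NA_real_, fit_rmse = NA_real_, fit_r2 = NA_real_,
                    accepted = FALSE, reject_reason = "")
  base_sel <- t < window$t_start + config$baseline_ms / 1000
  if (!any(base_sel)) base_sel <- seq_along(t) <= 2L
  diastolic <- mean(y[base_sel])
  base_sd <- stats::sd(y[base_sel])
  if (!is.finite(base_sd)) base_sd <- 0
  ys <- movingAverage(y, config$smooth_width)
  ipk <- which.max(ys)                       # earliest max wins
  peak <- ys[ipk]
  amplitude <- peak - diastolic
  out$diastolic <- diastolic; out$peak <- peak; out$amplitude <- amplitude
  if (amplitude <= config$noise_k * base_sd) {
    out$reject_reason <- "amplitude below noise floor"
    return(out)
  }
  out$accepted <- TRUE
  ref_t <- window$stim_time
  if (config$ttp_reference == "onset") {
    onset <- which(ys > diastolic + config$noise_k * base_sd)
    onset <- onset[onset <= ipk]
    if (length(onset)) ref_t <- t[onset[1]]
  }
  out$time_to_peak <- t[ipk] - ref_t
  if (ipk >= 3L) {
    i <- 2:(ipk)
    deriv <- (ys[pmin(i + 1L, length(ys))] - ys[i - 1L]) /
      ((pmin(i + 1L, length(ys)) - (i - 1L)) * dt)
    out$max_rate_of_rise <- max(deriv) / 1000   # per ms
  }
  # decay fit window
  istart <- ipk
  if (config$decay_start == "p90") {
    past <- which(ys <= diastolic + 0.9 * amplitude)
    past <- past[past > ipk]
    if (length(past)) istart <- past[1]
  }
  tfit0 <- t[istart] + config$decay_delay_s
  fit_sel <- t >= tfit0
  ft <- t[fit_sel]; fy <- y[fit_sel]
  fit <- fitMonoexp(ft, fy)
  if (fit$converged) {
    out$tau_decay <- fit$tau; out$fit_rmse <- fit$rmse; out$fit_r2 <- fit$r2
    if (config$peak_estimate == "fit" && config$decay_start == "peak" &&
        config$decay_delay_s == 0) {
      # fitted decay extrapolated to the peak time: exact on clean data,
      # no max-of-noise bias on noisy data
      out$peak <- fit$A + fit$C
      out$amplitude <- out$peak - diastolic
    }
  } else out$reject_reason <- fit$reason
  out
}

#' Analyze every beat of a paced recording
#'
#' Convenience composition of \code{\link{segmentBeats}} and
#' \code{\link{analyzeTransient}}.
#'
#' @inheritParams segmentBeats
#' @inheritParams analyzeTransient
#' @return data.frame of per-beat parameters (one row per beat window).
#' @export
analyzeBeats <- function(x, stim_freq = NULL, stim_times = NULL,
                         config = transientConfig()) {
  win <- segmentBeats(x, stim_freq, stim_times)
  do.call(rbind, lapply(seq_len(nrow(win)), function(i)
    analyzeTransient(x, win[i, ], config)))
}

#' Steady-state summary over the last accepted beats
#'
#' Mean and SEM of each kinetic parameter over the last \code{n_last}
#' accepted beats, emulating the experimental practice of reading out after
#' pacing has reached steady state.
#'
#' @param params data.frame from \code{\link{analyzeBeats}}.
#' @param n_last number of accepted beats to summarise.
#' @return A list with \code{summary} (data.frame: parameter, mean, sem),
#'   \code{n_beats}, \code{beats_used} and \code{rejected} (data.frame of
#'   rejected beat indices and reasons).
#' @export
steadyStateSummary <- function(params, n_last = 10L) {
  acc <- params[params$accepted & is.finite(params$tau_decay), , drop = FALSE]
  if (nrow(acc) < n_last)
    cfStop(sprintf("only %d accepted beats, need %d", nrow(acc), n_last),
           "cardioflux_summary_error")
  use <- acc[seq(nrow(acc) - n_last + 1L, nrow(acc)), , drop = FALSE]
  fields <- c("diastolic", "peak", "amplitude", "max_rate_of_rise",
              "time_to_peak", "tau_decay", "fit_rmse", "fit_r2")
  summ <- data.frame(parameter = fields,
                     mean = vapply(fields, function(f) mean(use[[f]]), 0),
                     sem = vapply(fields, function(f) sem(use[[f]]), 0),
                     row.names = NULL)
  rej <- params[!params$accepted, c("beat", "reject_reason"), drop = FALSE]
  list(summary = summ, n_beats = n_last, beats_used = use$beat, rejected = rej)
}

# Convenience lookup into a steadyStateSummary result.
ssMean <- function(ss, parameter) {
  ss$summary$mean[match(parameter, ss$summary$parameter)]
}
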