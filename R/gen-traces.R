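# Synthetic calcium-transient generation with exact, analytically known
# ground truth.

#' Solve the rise time constant of the product-of-exponentials kernel
#'
#' The kernel \code{g(t) = (1 - exp(-t/tau_r)) exp(-t/tau_d)} peaks at
#' \code{t* = tau_r log(1 + tau_d/tau_r)}, which increases monotonically in
#' \code{tau_r} toward the supremum \code{tau_d}: a requested time-to-peak is
#' reachable only when \code{ttp < tau_d}. Solved by \code{uniroot} on the
#' closed relation.
#'
#' @param ttp requested time-to-peak, s.
#' @param tau_decay decay time constant, s.
#' @param tol root tolerance.
#' @return \code{tau_r}, s.
#' @export
solveTauRise <- function(ttp, tau_decay, tol = 1e-12) {
  if (ttp <= 0 || tau_decay <= 0)
    cfStop("ttp and tau_decay must be > 0", "cardioflux_gen_error")
  if (ttp >= tau_decay)
    cfStop(sprintf(
      "unreachable time-to-peak: ttp (%.4g s) must be < tau_decay (%.4g s) for this kernel",
      ttp, tau_decay), "cardioflux_gen_error")
  tstar <- function(tr) tr * log1p(tau_decay / tr) - ttp
  lo <- ttp * 1e-6
  hi <- tau_decay * 1e6
  stats::uniroot(tstar, c(lo, hi), tol = tol)$root
}

#' Normalised transient kernel shapes
#'
#' Kernels are normalised so that the maximum is 1 exactly at \code{t = ttp}
#' and the kernel is 0 for \code{t < 0}. \code{"cosexp"} (default): a
#' half-cosine rise reaching 1 at \code{ttp}, then an exact monoexponential
#' decay with \code{tau_decay} -- every ground-truth parameter is
#' identifiable by the analyzer. \code{"expprod"}: the product
#' \code{(1 - exp(-t/tau_r)) exp(-t/tau_decay)} with \code{tau_r} solved
#' from \code{ttp} (\code{\link{solveTauRise}}); note its decay phase is a
#' two-exponential mixture until the rise factor saturates (see vignette).
#'
#' @param t time from the stimulus, s (vectorised; negative = 0).
#' @param ttp time-to-peak, s (measured from the stimulus).
#' @param tau_decay decay time constant, s.
#' @param kernel kernel family.
#' @param latency excitation-to-release latency, s: the kernel stays at 0
#'   for \code{t < latency} (the pre-upstroke baseline), then rises to peak
#'   at \code{ttp}. Must be < \code{ttp}.
#' @return Kernel values in [0, 1].
#' @export
transientKernel <- function(t, ttp, tau_decay, kernel = c("cosexp", "expprod"),
                            latency = 0) {
  kernel <- match.arg(kernel)
  if (latency >= ttp)
    cfStop("latency must be < ttp", "cardioflux_gen_error")
  g <- numeric(length(t))
  te <- t - latency
  ttpe <- ttp - latency
  pos <- te >= 0
  if (kernel == "cosexp") {
    rise <- pos & te < ttpe
    g[rise] <- 0.5 * (1 - cos(pi * te[rise] / ttpe))
    dec <- te >= ttpe
    g[dec] <- exp(-(te[dec] - ttpe) / tau_decay)
  } else {
    tr <- solveTauRise(ttpe, tau_decay)
    gmax <- (1 - exp(-ttpe / tr)) * exp(-ttpe / tau_decay)
    g[pos] <- (1 - exp(-te[pos] / tr)) * exp(-te[pos] / tau_decay) / gmax
  }
  g
}

#' Generate a paced synthetic calcium-transient recording
#'
#' Builds a fluorescence trace whose per-beat ground truth (diastolic level,
#' amplitude, time-to-peak, decay tau) is known exactly. Each beat adds a
#' normalised kernel (half-cosine rise peaking exactly at \code{ttp}, then a
#' monoexponential decay with \code{tau_decay}; see
#' \code{\link{transientKernel}} for the alternative product-of-exponentials
#' shape). Gaussian white noise and a linear drift (photobleaching surrogate)
#' are added on the signal scale.
#'
#' In single mode the emitted channel is
#' \code{F = f0_au (diastolic + amplitude g + drift + noise)} so that
#' \code{\link{computeDff}} with a pre-stimulus baseline window and a
#' \code{diastolic} of 0 recovers \code{amplitude} as dF/F0. In ratiometric
#' mode the target ratio \code{r(t)} is split anti-correlated into
#' \code{F340 = B r^s}, \code{F380 = B r^(s-1)} (channel split exponent
#' \code{s}), so the computed ratio reproduces the target transient exactly
#' at zero noise; channel noise is scaled to give approximately
#' \code{noise_sd} on the ratio at the diastolic level.
#'
#' @param n_beats number of beats.
#' @param stim_freq pacing frequency, Hz.
#' @param diastolic baseline signal level (ratio units, or dF/F0 = 0).
#' @param amplitude transient amplitude in signal units.
#' @param ttp time-to-peak, s.
#' @param tau_decay decay time constant, s.
#' @param noise_sd Gaussian noise SD on the signal scale.
#' @param drift linear drift, signal units per s.
#' @param sampling_rate Hz (default 400).
#' @param pre_s unpaced lead-in before the first stimulus, s (baseline for
#'   dF/F0).
#' @param mode \code{"single"} or \code{"ratiometric"}.
#' @param f0_au baseline fluorescence in single mode, a.u.
#' @param channel_base,channel_split ratiometric channel baseline (a.u.) and
#'   split exponent in [0, 1].
#' @param kernel see \code{\link{transientKernel}}.
#' @param latency excitation-to-release latency, s; the kernel is 0 within
#'   \code{latency} of each stimulus, keeping the analyzer's pre-upstroke
#'   baseline segment clean. Must be < \code{ttp}.
#' @param seed mandatory RNG seed.
#' @return A \linkS4class{FluorescenceTrace}; attribute \code{ground_truth}
#'   holds the configured parameters and per-beat stimulus times.
#' @export
genTransientTrace <- function(n_beats = 20L, stim_freq = 1, diastolic = 1,
                              amplitude = 0.5, ttp = 0.15, tau_decay = 0.27,
                              noise_sd = 0, drift = 0, sampling_rate = 400,
                              pre_s = 1, mode = c("single", "ratiometric"),
                              f0_au = 100, channel_base = 100,
                              channel_split = 0.5,
                              kernel = c("cosexp", "expprod"),
                              latency = 0.05, seed) {
  mode <- match.arg(mode)
  kernel <- match.arg(kernel)
  if (ttp <= 0 || tau_decay <= 0 || ttp >= 1 / stim_freq)
    cfStop("need 0 < ttp < stimulus period and tau_decay > 0",
           "cardioflux_gen_error")
  if (noise_sd < 0) cfStop("noise_sd must be >= 0", "cardioflux_gen_error")
  dt <- 1 / sampling_rate
  # one trailing sample so the final beat window [stim, stim + 1/f) closes
  t <- seq(0, pre_s + n_beats / stim_freq, by = dt)
  stim <- pre_s + (seq_len(n_beats) - 1L) / stim_freq
  sig <- rep(diastolic, length(t))
  for (s0 in stim) sig <- sig + amplitude * transientKernel(t - s0, ttp,
                                                           tau_decay, kernel,
                                                           latency)
  sig <- sig + drift * t
  withSeed(seed, {
    if (mode == "single") {
      # F = f0_au x signal: with the default diastolic of 1, dF/F0 computed
      # against the pre-stimulus baseline recovers `amplitude` exactly.
      f <- f0_au * (sig + noise_sd * stats::rnorm(length(t)))
      channels <- list(F = f)
    } else {
      if (any(sig <= 0))
        cfStop("ratiometric mode needs a strictly positive target ratio",
               "cardioflux_gen_error")
      r <- sig
      f340 <- channel_base * r^channel_split
      f380 <- channel_base * r^(channel_split - 1)
      if (noise_sd > 0) {
        d0 <- diastolic
        sd_ch <- noise_sd * channel_base / sqrt(d0 * (1 + d0^2))
        f340 <- f340 + sd_ch * stats::rnorm(length(t))
        f380 <- f380 + sd_ch * stats::rnorm(length(t))
      }
      channels <- list(F340 = f340, F380 = f380)
    }
    gt <- list(n_beats = n_beats, stim_freq = stim_freq, stim_times = stim,
               diastolic = diastolic, amplitude = amplitude, ttp = ttp,
               tau_decay = tau_decay, noise_sd = noise_sd, drift = drift,
               kernel = kernel, latency = latency, mode = mode, pre_s = pre_s,
               seed = seed)
    tr <- FluorescenceTrace(t, channels, samplingRate = sampling_rate,
                            stimFreq = stim_freq, stimTimes = stim,
                            meta = list(synthetic = TRUE))
    attr(tr, "ground_truth") <- gt
    tr
  })
}

#' Generate a synthetic caffeine-bolus transient
#'
#' Flat diastolic baseline; at the event time the signal ramps linearly over
#' \code{ramp_s} (0.5 s) to \code{diastolic + store_amplitude}, then decays
#' exponentially back to the diastolic level with \code{tau_efflux}. The
#' caffeine event is annotated on the trace.
#'
#' @param store_amplitude transient amplitude, ratio units.
#' @param tau_efflux decay time constant, s.
#' @param diastolic baseline ratio.
#' @param pre_s,post_s record length before/after the bolus, s. A
#'   \code{post_s} below 3 x \code{tau_efflux} triggers a truncated-decay
#'   warning (the fit would be biased).
#' @param ramp_s rise duration, s.
#' @param noise_sd Gaussian noise SD (ratio units).
#' @param sampling_rate Hz.
#' @param seed mandatory RNG seed.
#' @return A single-channel \linkS4class{FluorescenceTrace} scaled so its
#'   \code{F} channel equals the ratio signal (use
#'   \code{\link{caffeineRatioTrace}} to view it as a
#'   \linkS4class{RatioTrace}); attribute \code{ground_truth}.
#' @export
genCaffeineTrace <- function(store_amplitude = 0.59, tau_efflux = 6.07,
                             diastolic = 1, pre_s = 10, post_s = 40,
                             ramp_s = 0.5, noise_sd = 0, sampling_rate = 400,
                             seed) {
  if (store_amplitude < 0 || tau_efflux <= 0)
    cfStop("store_amplitude >= 0 and tau_efflux > 0 required",
           "cardioflux_gen_error")
  if (post_s < 3 * tau_efflux)
    cfWarn(sprintf("post_s (%.3g s) < 3 x tau_efflux (%.3g s): truncated decay biases the fit",
                   post_s, 3 * tau_efflux), "cardioflux_gen_warning")
  dt <- 1 / sampling_rate
  t <- seq(0, pre_s + post_s - dt, by = dt)
  tev <- pre_s
  tpk <- tev + ramp_s
  sig <- rep(diastolic, length(t))
  ramp <- t >= tev & t < tpk
  sig[ramp] <- diastolic + store_amplitude * (t[ramp] - tev) / ramp_s
  dec <- t >= tpk
  sig[dec] <- diastolic + store_amplitude * exp(-(t[dec] - tpk) / tau_efflux)
  withSeed(seed, {
    if (noise_sd > 0) sig <- sig + noise_sd * stats::rnorm(length(t))
    tr <- FluorescenceTrace(t, list(F = sig), samplingRate = sampling_rate,
                            modality = "single",
                            events = data.frame(label = "caffeine", time = tev,
                                                stringsAsFactors = FALSE),
                            meta = list(synthetic = TRUE))
    attr(tr, "ground_truth") <- list(store_amplitude = store_amplitude,
                                     tau_efflux = tau_efflux,
                                     diastolic = diastolic,
                                     caffeine_time = tev, peak_time = tpk,
                                     noise_sd = noise_sd, seed = seed)
    tr
  })
}

#' View a synthetic caffeine trace's channel as a ratio signal
#'
#' The generator stores the ratio-scale signal directly in the \code{F}
#' channel; this wraps it as a \linkS4class{RatioTrace} for
#' \code{\link{analyzeCaffeine}}.
#'
#' @param trace output of \code{\link{genCaffeineTrace}} (or any
#'   single-channel trace whose \code{F} is already on the ratio scale).
#' @return A \linkS4class{RatioTrace} with \code{kind = "ratio"}.
#' @export
caffeineRatioTrace <- function(trace) {
  makeRatioTrace(trace@time, trace@channels$F, kind = "ratio",
                 stimFreq = trace@stimFreq, stimTimes = trace@stimTimes,
                 events = trace@events)
}
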