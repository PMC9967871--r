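noiselessRatio <- function(...) {
  computeRatio(genTransientTrace(..., noise_sd = 0, mode = "ratiometric",
                                 seed = 1))
}

test_that("segmentBeats yields one half-open window per stimulus", {
  t <- seq(0, 10, by = 0.0025)
  x <- RatioTrace(t, rep(1, length(t)))
  w1 <- segmentBeats(x, stim_freq = 1)
  expect_equal(nrow(w1), 10L)
  expect_equal(w1$t_end - w1$t_start, rep(1, 10))
  w2 <- segmentBeats(x, stim_freq = 0.5)
  expect_equal(nrow(w2), 5L)
  expect_equal(w2$t_end - w2$t_start, rep(2, 5))
  # explicit stimulus times override the frequency
  w3 <- segmentBeats(x, stim_freq = 1, stim_times = c(0.5, 3.5, 6.5))
  expect_equal(w3$stim_time, c(0.5, 3.5, 6.5))
  expect_equal(w3$t_end, c(3.5, 6.5, 9.5))
  # recording shorter than one period
  xs <- RatioTrace(t[t < 0.5], rep(1, sum(t < 0.5)))
  expect_error(segmentBeats(xs, stim_freq = 1), "zero usable",
               class = "cardioflux_error")
})

test_that("noiseless transients are recovered across the parameter ranges", {
  cfg <- transientConfig(smooth_width = 1)
  cases <- expand.grid(amplitude = c(0.01, 0.5, 3),
                       tau = c(0.05, 0.27, 2),
                       ttp = c(0.05, 0.15, 0.5))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    period <- cs$ttp + 14 * cs$tau          # non-overlapping beats
    lat <- min(0.05, cs$ttp / 2)
    x <- noiselessRatio(n_beats = 3, stim_freq = 1 / period, diastolic = 1.2,
                        amplitude = cs$amplitude, ttp = cs$ttp,
                        tau_decay = cs$tau, latency = lat)
    pb <- analyzeBeats(x, config = transientConfig(
      smooth_width = 1, baseline_ms = lat * 1000))
    pb <- pb[pb$accepted, ]
    expect_equal(pb$diastolic, rep(1.2, nrow(pb)), tolerance = 1e-3)
    expect_equal(pb$amplitude, rep(cs$amplitude, nrow(pb)), tolerance = 1e-3)
    expect_equal(pb$time_to_peak, rep(cs$ttp, nrow(pb)), tolerance = 1e-3)
    expect_equal(pb$tau_decay, rep(cs$tau, nrow(pb)), tolerance = 1e-3)
    # rate of rise: analytic max slope of the half-cosine rise. A sampled
    # derivative carries an O((dt/rise)^2) discretisation error (sampling
    # bound, not a fitter defect), so the tolerance is 2%.
    ror_true <- cs$amplitude * pi / (2 * (cs$ttp - lat)) / 1000
    expect_equal(pb$max_rate_of_rise, rep(ror_true, nrow(pb)),
                 tolerance = 2e-2)
  }
})

test_that("fitted decay tau matches the log-linear oracle on clean decays", {
  t <- seq(0, 2, by = 0.0025)
  for (tau in c(0.1, 0.27, 0.8)) {
    y <- 1.3 + 0.6 * exp(-t / tau)
    fit <- fitMonoexp(t, y)
    expect_equal(fit$tau, logLinearTau(t, y, 1.3), tolerance = 1e-9)
    expect_equal(fit$tau, tau, tolerance = 1e-9)
  }
})

test_that("flat beats are rejected as below the noise floor", {
  t <- seq(0, 3, by = 0.0025)
  x <- RatioTrace(t, rep(1, length(t)))
  pb <- analyzeBeats(x, stim_freq = 1)
  expect_false(any(pb$accepted))
  expect_true(all(pb$reject_reason == "amplitude below noise floor"))
})

test_that("analysis is equivariant under time shifts", {
  x <- noiselessRatio(n_beats = 3, stim_freq = 0.5, amplitude = 0.5)
  dt <- 17.25
  shifted <- RatioTrace(traceTime(x) + dt, signalValues(x),
                        stimFreq = 0.5, stimTimes = stimTimes(x) + dt)
  p1 <- analyzeBeats(x)
  p2 <- analyzeBeats(shifted)
  for (f in c("diastolic", "amplitude", "time_to_peak", "tau_decay",
              "max_rate_of_rise"))
    expect_equal(p2[[f]], p1[[f]], tolerance = 1e-9)
})

test_that("constant offsets move the diastolic level but not the amplitude", {
  x <- noiselessRatio(n_beats = 3, stim_freq = 0.5, amplitude = 0.5)
  off <- 0.37
  x2 <- RatioTrace(traceTime(x), signalValues(x) + off,
                   stimFreq = 0.5, stimTimes = stimTimes(x))
  p1 <- analyzeBeats(x); p2 <- analyzeBeats(x2)
  expect_equal(p2$amplitude, p1$amplitude, tolerance = 1e-9)
  expect_equal(p2$diastolic, p1$diastolic + off, tolerance = 1e-9)
})

test_that("steady-state summary aggregates the last accepted beats", {
  x <- noiselessRatio(n_beats = 6, stim_freq = 0.5, amplitude = 0.5)
  pb <- analyzeBeats(x)
  ss <- steadyStateSummary(pb, n_last = 4)
  # identical beats: SEM 0 for every field
  expect_true(all(abs(ss$summary$sem) < 1e-9))
  expect_equal(ss$n_beats, 4)

  # SEM equals sd/sqrt(n) recomputed by hand on noisy beats
  xn <- computeRatio(genTransientTrace(n_beats = 8, stim_freq = 0.5,
                                       amplitude = 0.5, noise_sd = 0.01,
                                       mode = "ratiometric", seed = 9))
  pbn <- analyzeBeats(xn)
  ssn <- steadyStateSummary(pbn, n_last = 5)
  use <- pbn[pbn$accepted & is.finite(pbn$tau_decay), ]
  use <- use[(nrow(use) - 4):nrow(use), ]
  expect_equal(ssn$summary$sem[ssn$summary$parameter == "amplitude"],
               sd(use$amplitude) / sqrt(5))

  expect_error(steadyStateSummary(pb, n_last = 10), "accepted beats",
               class = "cardioflux_error")
})

test_that("mitochondrial transients peak later than cytosolic ones", {
  # paired kernels at the reported cytosolic (1 Hz) and mitochondrial
  # (0.1 Hz) time-to-peak values
  cyto <- noiselessRatio(n_beats = 3, stim_freq = 1, amplitude = 1.41,
                         ttp = 0.15, tau_decay = 0.27)
  mito <- computeDff(genTransientTrace(n_beats = 3, stim_freq = 0.1,
                                       amplitude = 0.033, ttp = 0.201,
                                       tau_decay = 0.3, noise_sd = 0,
                                       mode = "single", pre_s = 2, seed = 2),
                     c(0, 2))
  tc <- mean(analyzeBeats(cyto)$time_to_peak)
  tm <- mean(analyzeBeats(mito)$time_to_peak)
  expect_gt(tm, tc)
})

test_that("onset-referenced time-to-peak is shorter than stimulus-referenced", {
  x <- noiselessRatio(n_beats = 3, stim_freq = 0.5, amplitude = 0.5,
                      latency = 0.06)
  p_stim <- analyzeBeats(x)
  p_onset <- analyzeBeats(x, config = transientConfig(ttp_reference = "onset"))
  expect_true(all(p_onset$time_to_peak < p_stim$time_to_peak))
})
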