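test_that("readTrace parses a two-channel recording and infers the grid", {
  t <- seq(0, by = 1 / 400, length.out = 4000)
  f <- writeTraceCsv(tempfile(fileext = ".csv"), t,
                     F340 = 2 + 0.1 * sin(t), F380 = 1 + 0.05 * cos(t))
  tr <- readTrace(f)
  expect_s4_class(tr, "FluorescenceTrace")
  expect_identical(modality(tr), "ratiometric")
  expect_equal(samplingRate(tr), 400)
  expect_equal(diff(range(traceTime(tr))), 9.9975)
})

test_that("readTrace rejects malformed inputs with structured errors", {
  t <- seq(0, 1, by = 0.01)
  t2 <- t; t2[50] <- t2[49]          # duplicated timestamp
  f <- writeTraceCsv(tempfile(fileext = ".csv"), t2, F = t2 + 1)
  expect_error(readTrace(f), "non-uniform time grid",
               class = "cardioflux_error")
  f2 <- writeTraceCsv(tempfile(fileext = ".csv"), t, F340 = t + 1)
  expect_error(readTrace(f2), "F380", class = "cardioflux_error")
  df <- data.frame(time_s = t, F = t + 1); df$F[3] <- NA
  f3 <- tempfile(fileext = ".csv")
  write.csv(df, f3, row.names = FALSE)
  expect_error(readTrace(f3), "non-finite", class = "cardioflux_error")
})

test_that("trace, oxygraph and image formats round-trip write/read", {
  tr <- genTransientTrace(n_beats = 2, stim_freq = 1, noise_sd = 0.01,
                          mode = "ratiometric", seed = 4)
  f <- tempfile(fileext = ".csv")
  writeTrace(tr, f)
  tr2 <- readTrace(f)
  expect_equal(tr2@channels$F340, tr@channels$F340, tolerance = 1e-9)
  expect_equal(tr2@channels$F380, tr@channels$F380, tolerance = 1e-9)
  expect_equal(stimTimes(tr2), stimTimes(tr))
  expect_equal(stimFrequency(tr2), 1)
  expect_equal(samplingRate(tr2), samplingRate(tr))

  calib <- psiCalibration(tissueMass_mg = 2, cFCCP_uM = 2)
  rec <- genOxygraph(calib = calib, noise_sd = c(o2 = 0.2, safranine = 0.005),
                     seed = 5)
  fo <- tempfile(fileext = ".csv")
  writeOxygraph(rec, fo)
  rec2 <- readOxygraph(fo)
  expect_equal(rec2@o2, rec@o2, tolerance = 1e-9)
  expect_equal(rec2@safranine, rec@safranine, tolerance = 1e-9)
  expect_equal(rec2@events$label, rec@events$label)
  expect_equal(tissueMass(rec2), tissueMass(rec))

  img <- genClusterImage(density_um2 = 2, mean_area_um2 = 0.03, frame_um = 5,
                         seed = 6)
  fi <- tempfile(fileext = ".tif")
  writeLabelImage(img, fi)
  img2 <- readLabelImage(fi)
  expect_equal(imagePixels(img2), imagePixels(img), tolerance = 1e-6)
  expect_equal(pixelSize(img2), 15)
  expect_equal(channelLabel(img2), "TOM20")
})

test_that("computeRatio is pointwise F340/F380 and scale invariant", {
  t <- seq(0, 1, by = 0.01)
  tr <- FluorescenceTrace(t, list(F340 = rep(2, length(t)),
                                  F380 = rep(1, length(t))))
  expect_equal(signalValues(computeRatio(tr)), rep(2, length(t)))

  base <- 1 + 0.3 * abs(sin(5 * t)) + 0.1
  tr2 <- FluorescenceTrace(t, list(F340 = base * 1.1, F380 = base * 0.9))
  r1 <- signalValues(computeRatio(tr2))
  tr3 <- FluorescenceTrace(t, list(F340 = 3.7 * base * 1.1,
                                   F380 = 3.7 * base * 0.9))
  expect_equal(signalValues(computeRatio(tr3)), r1, tolerance = 1e-12)
  expect_equal(r1, rep(1.1 / 0.9, length(t)))

  tr4 <- FluorescenceTrace(t, list(F340 = base, F380 = base - 1.2))
  expect_error(computeRatio(tr4), "sample index",
               class = "cardioflux_error")
})

test_that("computeDff normalises to the baseline window", {
  t <- seq(0, 2, by = 0.005)
  tr <- FluorescenceTrace(t, list(F = rep(5, length(t))))
  expect_equal(signalValues(computeDff(tr, c(0, 0.5))), rep(0, length(t)))

  # peak dF/F0 example: f0 = 2, peak F = 2.066 -> 0.033
  f <- rep(2, length(t)); f[t >= 1 & t < 1.2] <- 2.066
  tr2 <- FluorescenceTrace(t, list(F = f))
  expect_equal(max(signalValues(computeDff(tr2, c(0, 0.5)))), 0.033)

  # adding a constant offset changes dF/F0 by the closed-form factor
  c0 <- 0.7
  tr3 <- FluorescenceTrace(t, list(F = f + c0))
  d3 <- signalValues(computeDff(tr3, c(0, 0.5)))
  expect_equal(max(d3), (2.066 - 2) / (2 + c0))
  # and the background argument undoes it
  d4 <- signalValues(computeDff(tr3, c(0, 0.5), background = c0))
  expect_equal(max(d4), 0.033)

  expect_error(computeDff(tr2, c(-1, 0.5)), "outside",
               class = "cardioflux_error")
  expect_error(computeDff(tr2, c(0, 0.004)), "10 samples",
               class = "cardioflux_error")
})

test_that("oxygraph reader validates event labels and order", {
  t <- 0:100
  df <- data.frame(time_s = t, o2_uM = 200 - 0.1 * t, safranine_uM = 0.5,
                   event = "")
  df$event[c(1, 31, 61, 91)] <- c("GMP", "ADP_HEX", "CACL2", "FCCP")
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  rec <- readOxygraph(f)
  expect_equal(traceEvents(rec)$label, c("GMP", "ADP_HEX", "CACL2", "FCCP"))

  df2 <- df; df2$event[31] <- "ROTENONE"
  write.csv(df2, f, row.names = FALSE)
  expect_error(readOxygraph(f), "allowed", class = "cardioflux_error")
})

test_that("label images carry physical frame metadata", {
  img <- LabelImage(matrix(0, 1000, 1000), pixelSize = 15,
                    channelLabel = "TOM20")
  expect_equal(frameSize(img), c(15, 15))
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0.5, 10, 10), f)
  expect_error(readLabelImage(f), "pixel size", class = "cardioflux_error")
})

test_that("inferred sampling rate matches the generator exactly", {
  for (sr in c(100, 400, 1000)) {
    tr <- genTransientTrace(n_beats = 2, stim_freq = 1, sampling_rate = sr,
                            noise_sd = 0, seed = 1)
    f <- tempfile(fileext = ".csv")
    writeTrace(tr, f)
    expect_equal(samplingRate(readTrace(f)), sr)
  }
})
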