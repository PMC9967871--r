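test_that("generators are deterministic functions of their seed", {
  a <- genTransientTrace(n_beats = 3, noise_sd = 0.02, mode = "ratiometric",
                         seed = 11)
  b <- genTransientTrace(n_beats = 3, noise_sd = 0.02, mode = "ratiometric",
                         seed = 11)
  expect_identical(a@channels, b@channels)
  c_ <- genTransientTrace(n_beats = 3, noise_sd = 0.02, mode = "ratiometric",
                          seed = 12)
  expect_false(identical(a@channels$F340, c_@channels$F340))

  i1 <- genClusterImage(density_um2 = 3, mean_area_um2 = 0.03, seed = 5)
  i2 <- genClusterImage(density_um2 = 3, mean_area_um2 = 0.03, seed = 5)
  expect_identical(imagePixels(i1), imagePixels(i2))

  calib <- psiCalibration(2, cFCCP_uM = 2)
  r1 <- genOxygraph(calib = calib, noise_sd = c(o2 = 0.1, safranine = 0.01),
                    seed = 7)
  r2 <- genOxygraph(calib = calib, noise_sd = c(o2 = 0.1, safranine = 0.01),
                    seed = 7)
  expect_identical(o2Concentration(r1), o2Concentration(r2))
})

test_that("the rise time constant solves the peak-time relation", {
  for (p in list(c(0.15, 0.27), c(0.05, 0.3), c(0.2, 0.25), c(0.3, 4))) {
    tr <- solveTauRise(p[1], p[2])
    expect_equal(tr, bisectTauRise(p[1], p[2]), tolerance = 1e-9)
    expect_equal(tr * log1p(p[2] / tr), p[1], tolerance = 1e-9)
  }
  # a time-to-peak at or beyond tau_decay is unreachable for this kernel
  expect_error(solveTauRise(0.3, 0.27), "unreachable",
               class = "cardioflux_error")
})

test_that("both kernels peak at the requested time with unit height", {
  t <- seq(-0.1, 2, by = 1e-4)
  for (k in c("cosexp", "expprod")) {
    g <- transientKernel(t, ttp = 0.15, tau_decay = 0.27, kernel = k,
                         latency = 0.05)
    expect_equal(max(g), 1, tolerance = 1e-6)
    expect_equal(t[which.max(g)], 0.15, tolerance = 1e-3)
    expect_true(all(g[t <= 0.04] == 0))   # quiescent during the latency
  }
})

test_that("ratiometric channel splitting reproduces the target ratio", {
  for (split in c(0.3, 0.5, 0.8)) {
    tr <- genTransientTrace(n_beats = 3, stim_freq = 0.5, amplitude = 0.5,
                            noise_sd = 0, mode = "ratiometric",
                            channel_split = split, seed = 2)
    single <- genTransientTrace(n_beats = 3, stim_freq = 0.5, amplitude = 0.5,
                                noise_sd = 0, mode = "single", f0_au = 1,
                                seed = 2)
    expect_equal(signalValues(computeRatio(tr)), single@channels$F,
                 tolerance = 1e-6)
  }
})

test_that("noise inflates the spread of fitted time constants", {
  tauSD <- function(noise) {
    taus <- sapply(1:30, function(s) {
      tr <- genCaffeineTrace(0.78, 4.75, noise_sd = noise, post_s = 30,
                             pre_s = 5, seed = s)
      analyzeCaffeine(caffeineRatioTrace(tr))$tau_efflux
    })
    sd(taus)
  }
  expect_gt(tauSD(0.04), tauSD(0.02))
})

test_that("the group-study manifest records draws around the configured means", {
  d <- file.path(tempdir(), "cf_manifest_study")
  on.exit(unlink(d, recursive = TRUE))
  genGroupStudy(d, n_cells = 12L, n_images = 2L, seed = 31)
  man <- jsonlite::read_json(file.path(d, "manifest.json"),
                             simplifyVector = TRUE)
  cells <- man$cells
  expect_equal(nrow(cells), 2 * 12 * 4)   # 2 groups x (pre + iso + caff + mito)
  defs <- studyDefaults()
  for (grp in c("CON", "MCT")) {
    st <- cells$store_amplitude[cells$group == grp &
                                  cells$assay == "caffeine"]
    mu <- defs$caffeine[[grp]]$store[1]
    sdv <- defs$caffeine[[grp]]$store[2]
    expect_lt(abs(mean(st) - mu), 3 * sdv / sqrt(length(st)) + 0.02)
  }
  # fixture files exist for every manifest entry
  expect_length(list.files(d, pattern = "^cyto_.*\\.csv$"), 48)
  expect_length(list.files(d, pattern = "^tom20_.*\\.tif$"), 4)
})
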