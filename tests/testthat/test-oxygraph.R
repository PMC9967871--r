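calib <- psiCalibration(tissueMass_mg = 2, cTotal_uM = 2, cFCCP_uM = 2)

linearRecording <- function(slope, duration = 300, volume = 2, mass = 2,
                            saf = 0.5) {
  t <- seq(0, duration, by = 1)
  OxygraphRecording(t, 200 + slope * t, rep(saf, length(t)),
                    events = data.frame(label = "GMP", time = 0,
                                        dose = NA_real_),
                    chamberVolume = volume, tissueMass = mass)
}

test_that("state windows open after the settle time and close at the next event", {
  t <- seq(0, 1100, by = 1)
  rec <- OxygraphRecording(t, 200 - 0.01 * t, rep(0.5, length(t)),
                           events = data.frame(
                             label = c("GMP", "ADP_HEX", "CACL2", "FCCP"),
                             time = c(0, 300, 600, 900),
                             dose = c(NA, NA, 0.3, NA)))
  st <- segmentStates(rec, settle = 60)
  expect_equal(st$label, c("CI_Leak", "CI_OXPHOS", "Ca_titration_1", "FCCP"))
  expect_equal(st$t_start, c(60, 360, 660, 960))
  expect_equal(st$t_end, c(300, 600, 900, 1100))
  expect_error(segmentStates(rec, settle = 400), "empty window",
               class = "cardioflux_error")
  rec2 <- OxygraphRecording(t, 200 - 0.01 * t, rep(0.5, length(t)),
                            events = data.frame(label = "ADP_HEX", time = 0,
                                                dose = NA_real_))
  expect_error(segmentStates(rec2), "GMP", class = "cardioflux_error")
})

test_that("flux follows the unit arithmetic of slope, volume and mass", {
  # -0.01 uM/s in a 2 mL chamber with 2 mg tissue -> 10 pmol s^-1 mg^-1
  rec <- linearRecording(-0.01)
  w <- list(t_start = 0, t_end = 300)
  expect_equal(as.numeric(computeFlux(rec, w)), 10, tolerance = 1e-12)
  expect_equal(as.numeric(computeFlux(linearRecording(0), w)), 0)
  # linear in chamber volume, inverse in tissue mass
  expect_equal(as.numeric(computeFlux(linearRecording(-0.01, volume = 4), w)),
               20, tolerance = 1e-12)
  expect_equal(as.numeric(computeFlux(linearRecording(-0.01, mass = 4), w)),
               5, tolerance = 1e-12)
  # a rising O2 trace is flagged but still quantified
  fpos <- computeFlux(linearRecording(0.01), w)
  expect_true(attr(fpos, "o2_increasing"))
  expect_equal(as.numeric(fpos), -10, tolerance = 1e-12)
})

test_that("noisy flux is recovered within 2 percent", {
  reps <- sapply(1:20, function(s) {
    rec <- genOxygraph(calib = calib, noise_sd = c(o2 = 0.05, safranine = 0),
                       seed = s)
    st <- segmentStates(rec, settle = 60)
    as.numeric(computeFlux(rec, st[2, ]))
  })
  truth <- 0.04 * 2 * 1000 / 2
  expect_lt(abs(median(reps) - truth) / truth, 0.02)
})

test_that("the noiseless protocol round-trips flux and psi exactly", {
  lad <- data.frame(cacl2_mM = 0.3, free_ca_uM = 0.39)
  rec <- genOxygraph(calib = calib, freeCaLadder = lad, seed = 1)
  gt <- attr(rec, "ground_truth")
  states <- analyzeOxygraph(rec, calib)
  expect_equal(states$flux, gt$flux, tolerance = 1e-9)
  expect_equal(states$psi, gt$psi, tolerance = 1e-6)
  expect_equal(states$psi[states$label == "FCCP"], 0)
  expect_equal(states$free_ca[states$label == "Ca_titration_1"], 0.39)
  expect_true(all(states$steady))
  # O2 mass balance: per-state concentration drop = slope x duration
  o2 <- o2Concentration(rec)
  expect_equal(o2[301] - o2[1], -0.01 * 300, tolerance = 1e-9)
})

test_that("a missing free-Ca ladder leaves titration states annotated unknown", {
  rec <- genOxygraph(calib = calib, seed = 2)
  states <- analyzeOxygraph(rec, calib)
  expect_true(is.na(states$free_ca[states$label == "Ca_titration_1"]))
  expect_false(anyNA(states$flux))
})

test_that("cFCCP can be estimated from the FCCP state", {
  rec <- genOxygraph(calib = calib, seed = 3)
  open_cal <- psiCalibration(tissueMass_mg = 2, cTotal_uM = 2)  # cFCCP = NA
  states <- analyzeOxygraph(rec, open_cal)
  expect_equal(states$psi[1], -210, tolerance = 1e-6)
})

test_that("generator refuses unphysical protocols", {
  bad <- oxygraphProtocol(); bad$psi[1] <- 50
  expect_error(genOxygraph(protocol = bad, calib = calib, seed = 1),
               "psi", class = "cardioflux_error")
  deep <- oxygraphProtocol(); deep$o2_slope <- rep(-1, 4)
  expect_error(genOxygraph(protocol = deep, calib = calib, seed = 1),
               "below zero", class = "cardioflux_error")
})

test_that("sustained safranine rise during Ca titration flags mPTP opening", {
  rec <- genOxygraph(calib = calib, seed = 4)
  expect_false(detectMptp(rec, calib)$opened)
  # inject an irreversible depolarisation: safranine climbs to the FCCP level
  saf <- safranine(rec)
  t <- traceTime(rec)
  ca <- t >= 660 & t < 900
  saf[ca] <- seq(saf[which(ca)[1] - 1], 1.95, length.out = sum(ca))
  saf[t >= 900] <- 1.95
  rec2 <- OxygraphRecording(t, o2Concentration(rec), saf,
                            events = traceEvents(rec),
                            chamberVolume = chamberVolume(rec),
                            tissueMass = tissueMass(rec))
  hit <- detectMptp(rec2, calib)
  expect_true(hit$opened)
  expect_true(hit$time >= 660 && hit$time <= 900)
})
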