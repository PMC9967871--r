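# Independent oracles used across the suite. These deliberately use naive
# routes (log-linear regression, bisection, O(n^2) scans) so they share no
# code path with the package's estimators.

# Decay time constant by log-linear regression with KNOWN offset.
logLinearTau <- function(t, y, offset) {
  sel <- y - offset > 0
  fit <- stats::lm(log(y[sel] - offset) ~ t[sel])
  -1 / unname(coef(fit)[2])
}

# Rise time constant of the product-of-exponentials kernel by bisection on
# t*(tau_r) = tau_r log(1 + tau_d/tau_r).
bisectTauRise <- function(ttp, tau_d, iters = 200) {
  f <- function(tr) tr * log1p(tau_d / tr) - ttp
  lo <- 1e-9; hi <- 1e6
  for (i in seq_len(iters)) {
    m <- (lo + hi) / 2
    if (f(m) > 0) hi <- m else lo <- m
  }
  (lo + hi) / 2
}

# Buffer concentration for a target potential by bracketed bisection on the
# forward Nernst conversion.
bisectInversePsi <- function(psi, calib, iters = 200) {
  cf <- calib@cFCCP
  lo <- cf * 1e-12; hi <- cf * (1 - 1e-12)
  for (i in seq_len(iters)) {
    m <- (lo + hi) / 2
    if (safranineToPsi(m, calib) > psi) hi <- m else lo <- m
  }
  (lo + hi) / 2
}

# All-pairs nearest neighbour scan.
bruteNND <- function(a, b = NULL) {
  self <- is.null(b)
  if (self) b <- a
  out <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    best <- Inf
    for (j in seq_len(nrow(b))) {
      if (self && i == j) next
      d <- sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2)
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

# Write a minimal ratio-trace CSV for the reader tests.
writeTraceCsv <- function(path, time, ...) {
  df <- data.frame(time_s = time, ...)
  write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE), path,
            row.names = FALSE, quote = FALSE)
  path
}

# Build a ClusterSet directly from centroid coordinates (single-pixel
# clusters), for tiling/NND tests that need exact geometry.
clusterSetFromPoints <- function(x, y, frame = c(15, 15), pixel_nm = 15) {
  s_um <- pixel_nm / 1000
  cl <- data.frame(id = seq_along(x), n_pixels = 1L, area_um2 = s_um^2,
                   x_um = x, y_um = y, edge = FALSE)
  new("ClusterSet", clusters = cl, source = "synthetic",
      channelLabel = "unknown", thresholdUsed = 0.5,
      thresholdMethod = "fixed", minSize = 1L, pixelSize = pixel_nm,
      frame = frame)
}
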