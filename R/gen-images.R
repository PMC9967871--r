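# Synthetic label-image generation with known spot ground truth.

# Hard-core placement. "uniform": rejection sampling (RSA); errors when the
# requested packing cannot be reached within the attempt budget. "grid":
# jittered square lattice (feasible up to much higher packing). "auto":
# uniform below a packing fraction of 0.35, lattice above.
.placeSpots <- function(n, frame, radii, gap_um, placement) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  rmax <- max(radii)
  phi <- sum(pi * (radii + gap_um / 2)^2) / (frame[1] * frame[2])
  if (placement == "auto") placement <- if (phi < 0.35) "uniform" else "grid"
  if (placement == "uniform") {
    xs <- numeric(n); ys <- numeric(n)
    placed <- 0L
    attempts <- 0L; budget <- 400L * n
    while (placed < n) {
      attempts <- attempts + 1L
      if (attempts > budget)
        cfStop(sprintf(
          "requested density infeasible under minimum separation (placed %d of %d)",
          placed, n), "cardioflux_gen_error")
      cx <- stats::runif(1, rmax, frame[1] - rmax)
      cy <- stats::runif(1, rmax, frame[2] - rmax)
      if (placed > 0L) {
        i <- seq_len(placed)
        dmin <- radii[i] + radii[placed + 1L] + gap_um
        if (any((xs[i] - cx)^2 + (ys[i] - cy)^2 < dmin^2)) next
      }
      placed <- placed + 1L
      xs[placed] <- cx; ys[placed] <- cy
    }
    cbind(x = xs, y = ys)
  } else {
    nx <- ceiling(sqrt(n * frame[1] / frame[2]))
    ny <- ceiling(n / nx)
    sx <- frame[1] / nx; sy <- frame[2] / ny
    centers <- expand.grid(ix = seq_len(nx) - 0.5, iy = seq_len(ny) - 0.5)
    pick <- sample.int(nrow(centers), n)
    # per-spot jitter bounded so neighbours keep their separation
    jmax <- pmax(0, (min(sx, sy) - (2 * radii + gap_um)) / (2 * sqrt(2)))
    cbind(x = centers$ix[pick] * sx + stats::runif(n, -jmax, jmax),
          y = centers$iy[pick] * sy + stats::runif(n, -jmax, jmax))
  }
}

#' Generate a synthetic cluster image
#'
#' Renders fluorescent label spots on a dark background: spot count Poisson
#' in the frame area at the requested density (or fixed via \code{count}),
#' areas lognormal around \code{mean_area_um2}, positions hard-core (spots do
#' not touch) with uniform rejection sampling or a jittered lattice at high
#' packing (see Details in the package vignette), plus Gaussian noise.
#'
#' Spot profiles: \code{"disk"} (default) renders a uniform-intensity disk of
#' the target area with a ~1-pixel logistic edge roll-off, so the half-max
#' isoline encloses the target area; \code{"gaussian"} renders an isotropic
#' Gaussian whose full width at half maximum is the diameter of the
#' equal-area disk.
#'
#' @param density_um2 spot density, um^-2 (ignored when \code{count} given).
#' @param mean_area_um2 mean spot area, um^2.
#' @param area_sigma lognormal sigma of the area distribution.
#' @param frame_um frame side length (square frame), um.
#' @param pixel_nm pixel size, nm.
#' @param count fixed spot count (overrides the Poisson draw).
#' @param amplitude spot peak intensity (a.u.).
#' @param background constant background level.
#' @param noise_sd Gaussian noise SD.
#' @param profile \code{"disk"} or \code{"gaussian"}.
#' @param placement \code{"auto"}, \code{"uniform"} (reject-and-resample) or
#'   \code{"grid"} (jittered lattice).
#' @param gap_px minimum edge-to-edge separation, px.
#' @param channel_label label recorded on the image.
#' @param seed mandatory RNG seed.
#' @return A \linkS4class{LabelImage}; attribute \code{ground_truth} is a
#'   data.frame of spot centres (um), radii and areas plus the settings.
#' @export
genClusterImage <- function(density_um2 = 11.2, mean_area_um2 = 0.034,
                            area_sigma = 0.25, frame_um = 15, pixel_nm = 15,
                            count = NULL, amplitude = 1, background = 0,
                            noise_sd = 0.02,
                            profile = c("disk", "gaussian"),
                            placement = c("auto", "uniform", "grid"),
                            gap_px = 3, channel_label = "TOM20", seed) {
  profile <- match.arg(profile)
  placement <- match.arg(placement)
  frame <- c(frame_um, frame_um)
  s_um <- pixel_nm / 1000
  npx <- round(frame_um / s_um)
  withSeed(seed, {
    n <- if (is.null(count)) stats::rpois(1, density_um2 * frame[1] * frame[2])
         else as.integer(count)
    mu <- log(mean_area_um2) - area_sigma^2 / 2
    areas <- stats::rlnorm(n, mu, area_sigma)
    radii <- sqrt(areas / pi)
    gap_um <- gap_px * s_um
    # Lattice placement clamps oversized draws into their cell, then rescales
    # the size distribution so the realized mean area still matches the
    # request (feasible while the cap exceeds the target mean).
    if (placement != "uniform" && n > 0L) {
      nx <- ceiling(sqrt(n)); cell <- frame_um / nx
      rcap <- (cell - gap_um) / 2 - s_um / 2
      radii <- pmin(radii, rcap)
      if (pi * rcap^2 > mean_area_um2) {
        for (it in 1:8) {
          f <- mean_area_um2 / mean(pi * radii^2)
          if (abs(f - 1) < 0.005) break
          radii <- pmin(radii * sqrt(f), rcap)
        }
      }
      areas <- pi * radii^2
    }
    pos <- .placeSpots(n, frame, radii, gap_um, placement)
    px <- matrix(background, npx, npx)
    if (n > 0L) {
      edge_w <- 0.7 * s_um   # logistic edge roll-off (~1 px)
      for (k in seq_len(n)) {
        r <- radii[k]
        half <- r + 4 * edge_w
        c0 <- max(1L, floor((pos[k, "x"] - half) / s_um) + 1L)
        c1 <- min(npx, ceiling((pos[k, "x"] + half) / s_um))
        r0 <- max(1L, floor((pos[k, "y"] - half) / s_um) + 1L)
        r1 <- min(npx, ceiling((pos[k, "y"] + half) / s_um))
        if (c1 < c0 || r1 < r0) next
        xc <- (seq(c0, c1) - 0.5) * s_um - pos[k, "x"]
        yc <- (seq(r0, r1) - 0.5) * s_um - pos[k, "y"]
        rho <- sqrt(outer(yc^2, xc^2, "+"))
        spot <- if (profile == "disk")
          amplitude / (1 + exp((rho - r) / edge_w))
        else
          amplitude * exp(-rho^2 * log(2) / r^2)   # half max at rho = r
        px[r0:r1, c0:c1] <- px[r0:r1, c0:c1] + spot
      }
    }
    if (noise_sd > 0) px <- px + noise_sd * stats::rnorm(length(px))
    img <- LabelImage(px, pixel_nm, channel_label)
    attr(img, "ground_truth") <- list(
      spots = data.frame(x_um = pos[, "x"], y_um = pos[, "y"],
                         radius_um = radii, area_um2 = areas),
      density_um2 = if (is.null(count)) density_um2 else
        n / (frame[1] * frame[2]),
      mean_area_um2 = mean_area_um2, profile = profile,
      placement = placement, noise_sd = noise_sd, seed = seed)
    img
  })
}

#' Generate a striped binary mask with an exact fill fraction
#'
#' Horizontal stripes (myofibril-like banding) whose "on" rows are chosen by
#' Bresenham accumulation so the foreground fraction equals the request to
#' within one row in the frame. Used to exercise fractional-area estimation
#' with known ground truth.
#'
#' @param fill_fraction target foreground fraction (0-1).
#' @param frame_um frame side, um. @param pixel_nm pixel size, nm.
#' @param period_px stripe period, px.
#' @param amplitude,background on/off intensities. @param noise_sd Gaussian
#'   noise SD. @param channel_label label. @param seed RNG seed (only used
#'   when noise_sd > 0).
#' @return A \linkS4class{LabelImage}; attribute \code{ground_truth} records
#'   the realised fill fraction.
#' @export
genFillMask <- function(fill_fraction, frame_um = 15, pixel_nm = 15,
                        period_px = 20L, amplitude = 1, background = 0,
                        noise_sd = 0, channel_label = "phalloidin",
                        seed = 1) {
  if (fill_fraction < 0 || fill_fraction > 1)
    cfStop("fill_fraction must be in [0, 1]", "cardioflux_gen_error")
  s_um <- pixel_nm / 1000
  npx <- round(frame_um / s_um)
  on_per_period <- fill_fraction * period_px
  row_ids <- seq_len(npx) - 1L
  acc_hi <- floor((row_ids %/% period_px + 1) * on_per_period)
  acc_lo <- floor((row_ids %/% period_px) * on_per_period)
  pos_in <- row_ids %% period_px
  on <- pos_in < (acc_hi - acc_lo)   # first k rows of each period, k accumulated
  # exact target: adjust with global Bresenham over rows
  want <- round(fill_fraction * npx)
  if (sum(on) != want) {
    on <- rep(FALSE, npx)
    acc <- floor(seq_len(npx) * want / npx) - floor((seq_len(npx) - 1) * want / npx)
    on <- acc > 0
  }
  px <- matrix(background, npx, npx)
  px[on, ] <- amplitude
  withSeed(seed, {
    if (noise_sd > 0) px <- px + noise_sd * stats::rnorm(length(px))
    img <- LabelImage(px, pixel_nm, channel_label)
    attr(img, "ground_truth") <- list(fill_fraction = sum(on) / npx,
                                      requested = fill_fraction)
    img
  })
}
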