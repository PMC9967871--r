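fixed05 <- clusterConfig(threshold = "fixed", threshold_value = 0.5)

test_that("blank and sub-threshold images give empty cluster sets", {
  img <- LabelImage(matrix(0, 200, 200), 15, "TOM20")
  expect_equal(nClusters(segmentClusters(img)), 0L)
  img2 <- LabelImage(matrix(0.1, 200, 200), 15, "TOM20")
  expect_warning(cs <- segmentClusters(img2, clusterConfig(
    threshold = "fixed", threshold_value = 0.9)),
    class = "cardioflux_warning")
  expect_equal(nClusters(cs), 0L)
})

test_that("a single rendered disk has the expected pixelised area", {
  img <- genClusterImage(count = 1, mean_area_um2 = pi * 0.1^2,
                         area_sigma = 0, frame_um = 3, noise_sd = 0,
                         placement = "uniform", seed = 8)
  cs <- segmentClusters(img, fixed05)
  expect_equal(nClusters(cs), 1L)
  expect_lt(abs(clusters(cs)$area_um2 - pi * 0.1^2) / (pi * 0.1^2), 0.15)
  # brute-force oracle: pixels whose centre lies within the disk
  gt <- attr(img, "ground_truth")$spots
  s <- 15 / 1000
  n <- nrow(imagePixels(img))
  cx <- (col(imagePixels(img)) - 0.5) * s
  cy <- (row(imagePixels(img)) - 0.5) * s
  inside <- sum((cx - gt$x_um)^2 + (cy - gt$y_um)^2 <= gt$radius_um^2)
  expect_lt(abs(clusters(cs)$n_pixels - inside), 0.1 * inside + 20)
})

test_that("well-separated spots are counted exactly", {
  img <- genClusterImage(density_um2 = 2, mean_area_um2 = 0.03, noise_sd = 0,
                         seed = 21)
  cs <- segmentClusters(img, fixed05)
  expect_equal(nClusters(cs), nrow(attr(img, "ground_truth")$spots))
})

test_that("labelling uses 8-connectivity with a minimum size filter", {
  px <- matrix(0, 20, 20)
  px[5, 5] <- 1; px[6, 6] <- 1; px[7, 7] <- 1     # diagonal chain
  px[15, 15] <- 1                                  # isolated single pixel
  img <- LabelImage(px, 15, "RyR2")
  cs <- segmentClusters(img, clusterConfig(threshold = "fixed",
                                           threshold_value = 0.5,
                                           min_size = 1L))
  expect_equal(nClusters(cs), 2L)                  # chain merged, singleton kept
  expect_setequal(clusters(cs)$n_pixels, c(3L, 1L))
  cs4 <- segmentClusters(img, clusterConfig(threshold = "fixed",
                                            threshold_value = 0.5,
                                            min_size = 2L))
  expect_equal(nClusters(cs4), 1L)                 # singleton filtered out
})

test_that("cluster density tiles the frame and conserves counts", {
  # 225 clusters on a uniform 15 x 15 grid -> exactly 1 per 1 um^2 tile
  g <- expand.grid(x = seq(0.5, 14.5, by = 1), y = seq(0.5, 14.5, by = 1))
  cs <- clusterSetFromPoints(g$x, g$y)
  d <- clusterDensity(cs, tile_um2 = 1)
  expect_equal(d$mean_per_tile, 1)
  expect_true(all(d$counts == 1L))
  expect_equal(sum(d$counts), d$n_assigned)

  # conservation holds for arbitrary point patterns
  set.seed(33)
  cs2 <- clusterSetFromPoints(runif(400, 0, 15), runif(400, 0, 15))
  d2 <- clusterDensity(cs2)
  expect_equal(sum(d2$counts), d2$n_assigned)
  expect_equal(d2$n_assigned, 400L)
})

test_that("fractional area matches known fills and complements", {
  half <- matrix(0, 100, 100); half[1:50, ] <- 1
  img <- LabelImage(half, 15, "phalloidin")
  expect_equal(fractionalArea(img, config = fixed05), 50)
  comp <- LabelImage(1 - half, 15, "phalloidin")
  expect_equal(fractionalArea(comp, config = fixed05), 50)
  expect_equal(fractionalArea(img, config = fixed05) +
                 fractionalArea(comp, config = fixed05), 100)

  m <- genFillMask(0.597, seed = 1)
  expect_lt(abs(fractionalArea(m) - 59.7), 2)

  # raising a fixed threshold never increases the fractional area
  img3 <- genClusterImage(density_um2 = 5, mean_area_um2 = 0.03,
                          noise_sd = 0.05, seed = 12)
  fas <- sapply(c(0.2, 0.4, 0.6, 0.8), function(th)
    fractionalArea(img3, config = clusterConfig(threshold = "fixed",
                                                threshold_value = th)))
  expect_true(all(diff(fas) <= 0))
})

test_that("ROI-restricted fractional area follows the polygon", {
  half <- matrix(0, 100, 100); half[1:50, ] <- 1   # top half bright (y < 0.75)
  img <- LabelImage(half, 15, "phalloidin")
  top <- cbind(c(0, 1.5, 1.5, 0), c(0, 0, 0.75, 0.75))
  expect_equal(fractionalArea(img, roi = top, config = fixed05), 100)
  expect_error(fractionalArea(img, roi = cbind(c(10, 11, 11), c(10, 10, 11)),
                              config = fixed05),
               "ROI", class = "cardioflux_error")
})

test_that("nearest-neighbour distances agree with the all-pairs oracle", {
  two <- clusterSetFromPoints(c(1, 1.5), c(2, 2))
  expect_equal(nearestNeighbourDistances(two), c(0.5, 0.5))
  one <- clusterSetFromPoints(3, 3)
  expect_error(nearestNeighbourDistances(one), "self-exclusion",
               class = "cardioflux_error")

  set.seed(14)
  a <- cbind(runif(100, 0, 15), runif(100, 0, 15))
  b <- cbind(runif(60, 0, 15), runif(60, 0, 15))
  expect_identical(nearestNeighbourDistances(a), bruteNND(a))
  expect_identical(nearestNeighbourDistances(a, b), bruteNND(a, b))
})

test_that("segmentation is invariant to whole-pixel translations", {
  img <- genClusterImage(density_um2 = 1.5, mean_area_um2 = 0.03,
                         frame_um = 8, noise_sd = 0, placement = "uniform",
                         seed = 17)
  px <- imagePixels(img)
  n <- nrow(px)
  embed <- function(dr, dc) {            # same content, different offset
    canvas <- matrix(0, n + 60, n + 60)
    canvas[dr + seq_len(n), dc + seq_len(n)] <- px
    canvas
  }
  cs1 <- segmentClusters(LabelImage(embed(1, 1), 15, "TOM20"), fixed05)
  cs2 <- segmentClusters(LabelImage(embed(41, 28), 15, "TOM20"), fixed05)
  expect_equal(nClusters(cs2), nClusters(cs1))
  expect_equal(sort(clusters(cs2)$area_um2), sort(clusters(cs1)$area_um2))
  expect_equal(sort(nearestNeighbourDistances(cs2)),
               sort(nearestNeighbourDistances(cs1)), tolerance = 1e-9)
})

test_that("cluster areas conserve the thresholded foreground", {
  img <- genClusterImage(density_um2 = 4, mean_area_um2 = 0.03,
                         noise_sd = 0.02, seed = 19)
  bin_area <- sum(imagePixels(img) > 0.5) * (15 / 1000)^2
  cs_all <- segmentClusters(img, clusterConfig(threshold = "fixed",
                                               threshold_value = 0.5,
                                               min_size = 1L))
  expect_equal(sum(clusters(cs_all)$area_um2), bin_area, tolerance = 1e-9)
  cs_f <- segmentClusters(img, fixed05)
  expect_lte(sum(clusters(cs_f)$area_um2), bin_area)
})
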