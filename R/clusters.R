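# Cluster segmentation and spatial statistics for STED/confocal label images.

#' Configuration for cluster segmentation
#'
#' @param threshold \code{"otsu"} (default) or \code{"fixed"}.
#' @param threshold_value intensity threshold when \code{threshold="fixed"}.
#' @param min_size smallest cluster retained, px (default 4: removes
#'   single-pixel shot noise; two orders of magnitude below the smallest
#'   reported clusters at 15 nm pixels).
#' @param background_radius radius (px) of the grey-morphology (opening)
#'   background estimate subtracted before thresholding; 0 disables it.
#' @return A named list of class \code{cardioflux_config}.
#' @export
clusterConfig <- function(threshold = c("otsu", "fixed"),
                          threshold_value = NULL, min_size = 4L,
                          background_radius = 0) {
  threshold <- match.arg(threshold)
  if (threshold == "fixed" && is.null(threshold_value))
    cfStop("fixed thresholding needs threshold_value", "cardioflux_cluster_error")
  structure(list(threshold = threshold, threshold_value = threshold_value,
                 min_size = as.integer(min_size),
                 background_radius = background_radius),
            class = "cardioflux_config")
}

# Union-find with path halving; merges 4-connected EBImage labels across
# diagonal adjacencies to obtain 8-connected components.
.unionFind <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs)) for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  vapply(seq_len(n), find, 0L)
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels touching
# only diagonally are merged afterwards.
.label8 <- function(bin) {
  lab <- EBImage::bwlabel(bin)
  nlab <- max(lab)
  if (nlab < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  if (!nrow(pairs)) return(lab)
  root <- .unionFind(nlab, unique(pairs))
  relabel <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relabel[lab[lab > 0]]
  out
}

.resolveThreshold <- function(px, config) {
  if (config$threshold == "fixed") return(config$threshold_value)
  rng <- range(px)
  if (rng[2] <= rng[1]) return(Inf)  # constant image: nothing above threshold
  EBImage::otsu(EBImage::Image(px), range = rng)
}

#' Segment label clusters in a microscopy image
#'
#' Optional grey-morphology background subtraction, global thresholding
#' (Otsu by default; the method used is recorded in the result for
#' provenance), 8-connected component labelling, and removal of components
#' below \code{min_size} pixels. Areas are pixel counts times the pixel
#' area; centroids are pixel-center means in physical um coordinates
#' (x along columns, y along rows, origin at the top-left frame corner).
#' Clusters touching the frame border are retained but flagged \code{edge}.
#'
#' An all-zero image yields an empty \linkS4class{ClusterSet} (not an
#' error); a threshold at or above the maximum intensity yields an empty set
#' with a warning.
#'
#' @param img a \linkS4class{LabelImage}.
#' @param config see \code{\link{clusterConfig}}.
#' @return A \linkS4class{ClusterSet}.
#' @export
segmentClusters <- function(img, config = clusterConfig()) {
  stopifnot(is(img, "LabelImage"))
  px <- img@pixels
  if (config$background_radius > 0) {
    brush <- EBImage::makeBrush(2 * ceiling(config$background_radius) + 1, "disc")
    px <- px - EBImage::opening(px, brush)
  }
  emptySet <- function(thr) new("ClusterSet",
    clusters = data.frame(id = integer(0), n_pixels = integer(0),
                          area_um2 = numeric(0), x_um = numeric(0),
                          y_um = numeric(0), edge = logical(0)),
    source = "", channelLabel = img@channelLabel, thresholdUsed = thr,
    thresholdMethod = config$threshold, minSize = config$min_size,
    pixelSize = img@pixelSize, frame = img@frame)
  if (all(px == 0)) return(emptySet(0))
  thr <- .resolveThreshold(px, config)
  if (thr >= max(px)) {
    cfWarn("threshold at or above maximum intensity: no clusters",
           "cardioflux_threshold_warning")
    return(emptySet(thr))
  }
  lab <- .label8(px > thr)
  nlab <- max(lab)
  if (nlab == 0L) return(emptySet(thr))
  sizes <- tabulate(lab[lab > 0], nbins = nlab)
  keep <- which(sizes >= config$min_size)
  if (!length(keep)) return(emptySet(thr))
  idx <- which(lab > 0)
  l <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  cx <- rowsum(as.numeric(cols), l)[, 1] / sizes
  cy <- rowsum(as.numeric(rows), l)[, 1] / sizes
  on_edge <- rowsum(as.numeric(rows == 1L | rows == nrow(lab) |
                                 cols == 1L | cols == ncol(lab)), l)[, 1] > 0
  s_um <- img@pixelSize / 1000
  cl <- data.frame(id = seq_along(keep), n_pixels = sizes[keep],
                   area_um2 = sizes[keep] * s_um^2,
                   x_um = (cx[keep] - 0.5) * s_um,
                   y_um = (cy[keep] - 0.5) * s_um,
                   edge = on_edge[keep])
  new("ClusterSet", clusters = cl, source = "",
      channelLabel = img@channelLabel, thresholdUsed = thr,
      thresholdMethod = config$threshold, minSize = config$min_size,
      pixelSize = img@pixelSize, frame = img@frame)
}

#' Cluster density per tile
#'
#' Tiles the frame from the origin into square tiles of the requested area
#' (partial tiles at the right/bottom edge are excluded) and assigns each
#' cluster to the tile containing its centroid. The mean count per tile is
#' the "clusters per 1 um^2" readout when \code{tile_um2 = 1}.
#'
#' @param cs a \linkS4class{ClusterSet}.
#' @param tile_um2 tile area, um^2 (default 1).
#' @return A list: \code{counts} (matrix of per-tile counts, rows = y),
#'   \code{mean_per_tile}, \code{tile_um2}, \code{n_assigned}.
#' @export
clusterDensity <- function(cs, tile_um2 = 1) {
  stopifnot(is(cs, "ClusterSet"))
  side <- sqrt(tile_um2)
  nx <- floor(cs@frame[1] / side + 1e-9)
  ny <- floor(cs@frame[2] / side + 1e-9)
  if (nx < 1L || ny < 1L)
    cfStop("tile larger than frame", "cardioflux_cluster_error")
  cl <- cs@clusters
  ix <- floor(cl$x_um / side) + 1L
  iy <- floor(cl$y_um / side) + 1L
  keep <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
  counts <- matrix(0L, nrow = ny, ncol = nx)
  if (any(keep)) {
    tab <- table(factor(iy[keep], levels = seq_len(ny)),
                 factor(ix[keep], levels = seq_len(nx)))
    counts <- matrix(as.integer(tab), nrow = ny, ncol = nx)
  }
  list(counts = counts, mean_per_tile = mean(counts), tile_um2 = tile_um2,
       n_assigned = sum(keep))
}

#' Fractional labelled area within a region of interest
#'
#' Percentage of ROI pixels above threshold, using the same thresholding
#' configuration as \code{\link{segmentClusters}}. The ROI is a polygon in
#' physical um coordinates (matrix with columns x, y); \code{NULL} means the
#' full frame.
#'
#' @param img a \linkS4class{LabelImage}.
#' @param roi polygon vertex matrix (um) or \code{NULL}.
#' @param config see \code{\link{clusterConfig}}.
#' @return Percent of ROI area above threshold (0-100).
#' @export
fractionalArea <- function(img, roi = NULL, config = clusterConfig()) {
  stopifnot(is(img, "LabelImage"))
  px <- img@pixels
  thr <- .resolveThreshold(px, config)
  bin <- px > thr
  if (is.null(roi)) return(100 * mean(bin))
  s_um <- img@pixelSize / 1000
  # pixel centers in um
  cx <- (col(px) - 0.5) * s_um
  cy <- (row(px) - 0.5) * s_um
  inside <- mgcv::in.out(rbind(as.matrix(roi), as.matrix(roi)[1, ]),
                         cbind(as.vector(cx), as.vector(cy)))
  if (!any(inside))
    cfStop("degenerate ROI: no pixels inside", "cardioflux_cluster_error")
  100 * mean(bin[inside])
}

#' Nearest-neighbour distances between cluster centroids
#'
#' For every cluster in \code{a}, the distance (um) to the nearest centroid
#' in \code{b}. When \code{b} is omitted the distances are within \code{a}
#' with self-exclusion (a cluster is not its own neighbour).
#'
#' @param a,b \linkS4class{ClusterSet}s (or 2-column matrices of um
#'   coordinates).
#' @return Numeric vector, one distance per cluster in \code{a}.
#' @export
nearestNeighbourDistances <- function(a, b = NULL) {
  coords <- function(x) if (is(x, "ClusterSet"))
    cbind(x@clusters$x_um, x@clusters$y_um) else as.matrix(x)
  pa <- coords(a)
  self <- is.null(b)
  pb <- if (self) pa else coords(b)
  if (!nrow(pb) || (self && nrow(pa) < 2L))
    cfStop("no neighbours available (empty target set after self-exclusion)",
           "cardioflux_cluster_error")
  d2 <- outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2
  if (self) diag(d2) <- Inf
  sqrt(apply(d2, 1, min))
}
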