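#' Construct a LabelImage
#'
#' @param pixels numeric intensity matrix; row 1 / column 1 is the top-left
#'   pixel, physical x runs along columns.
#' @param pixelSize pixel edge length, nm (15 for the STED frames, 50-80 for
#'   confocal).
#' @param channelLabel one of \code{TOM20}, \code{RyR2}, \code{phalloidin},
#'   \code{unknown}.
#' @return A validated \linkS4class{LabelImage}; the physical frame (um) is
#'   derived as shape x pixel size.
#' @export
LabelImage <- function(pixels, pixelSize, channelLabel = "unknown") {
  new("LabelImage", pixels = pixels, pixelSize = pixelSize,
      channelLabel = channelLabel,
      frame = c(ncol(pixels), nrow(pixels)) * pixelSize / 1000)
}

#' Read a 2-D microscopy image from TIFF
#'
#' The pixel size is required: it comes from the \code{pixel_size_nm}
#' argument, or from a JSON sidecar next to the file (fields
#' \code{pixel_size_nm}, \code{channel_label}, and optional
#' \code{intensity_scale}/\code{intensity_offset} written by
#' \code{\link{writeLabelImage}} to undo the unit-range normalisation TIFF
#' storage imposes).
#'
#' @param path TIFF path.
#' @param pixel_size_nm pixel size override, nm.
#' @param channel for multi-channel TIFFs, the channel index to extract.
#' @param channel_label label override.
#' @return A \linkS4class{LabelImage}.
#' @export
readLabelImage <- function(path, pixel_size_nm = NULL, channel = 1L,
                           channel_label = NULL) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3L) px <- px[, , channel]
  sc <- readSidecar(path)
  if (is.null(pixel_size_nm)) pixel_size_nm <- sc$pixel_size_nm
  if (is.null(pixel_size_nm))
    cfStop("missing pixel size: supply pixel_size_nm or a JSON sidecar",
           "cardioflux_io_error")
  if (is.null(channel_label))
    channel_label <- if (!is.null(sc$channel_label)) sc$channel_label else "unknown"
  if (!is.null(sc$intensity_scale))
    px <- px * sc$intensity_scale + if (!is.null(sc$intensity_offset))
      sc$intensity_offset else 0
  LabelImage(px, pixel_size_nm, channel_label)
}

#' Write a LabelImage to 32-bit float TIFF plus JSON sidecar
#'
#' Intensities are affinely mapped into [0, 1] for storage; the mapping is
#' recorded in the sidecar so \code{\link{readLabelImage}} restores the
#' original values.
#'
#' @param img a \linkS4class{LabelImage}. @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeLabelImage <- function(img, path) {
  px <- img@pixels
  rng <- range(px)
  offset <- rng[1]
  scale <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
  tiff::writeTIFF((px - offset) / scale, path, bits.per.sample = 32L)
  jsonlite::write_json(list(pixel_size_nm = img@pixelSize,
                            channel_label = img@channelLabel,
                            intensity_scale = scale, intensity_offset = offset),
                       jsonSidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
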