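#' @import methods
NULL

.EVENT_LABELS_OXY <- c("GMP", "ADP_HEX", "CACL2", "FCCP")
.CHANNEL_LABELS <- c("TOM20", "RyR2", "phalloidin", "unknown")

emptyEvents <- function() data.frame(label = character(0), time = numeric(0),
                                     stringsAsFactors = FALSE)

#' FluorescenceTrace: raw acquired fluorescence channels for one cell
#'
#' Container for a uniformly sampled fluorescence recording: either the two
#' Fura-2 excitation channels (\code{F340}, \code{F380}) on one time grid, or
#' a single channel \code{F} (e.g. Rhod-2). Stimulation metadata (pacing
#' frequency and/or explicit stimulus times) and labelled events (e.g. a
#' caffeine bolus) travel with the data.
#'
#' @slot time numeric, seconds, strictly increasing uniform grid (0-based).
#' @slot channels named list of numeric intensity vectors (a.u.), each the
#'   same length as \code{time}; names are \code{F340}/\code{F380} for
#'   ratiometric recordings or \code{F} for single-channel ones.
#' @slot samplingRate numeric, Hz.
#' @slot modality \code{"ratiometric"} or \code{"single"}.
#' @slot stimFreq numeric, Hz; 0 means unpaced.
#' @slot stimTimes numeric, seconds; optional explicit stimulus times.
#' @slot events data.frame with columns \code{label}, \code{time}.
#' @slot meta list of free-form metadata (cell id, group, condition).
#'
#' @exportClass FluorescenceTrace
setClass("FluorescenceTrace",
  representation(time = "numeric", channels = "list", samplingRate = "numeric",
                 modality = "character", stimFreq = "numeric",
                 stimTimes = "numeric", events = "data.frame", meta = "list"))

setValidity("FluorescenceTrace", function(object) {
  msgs <- character(0)
  t <- object@time
  if (length(t) < 2L) return("time must have at least 2 samples")
  dt <- diff(t)
  if (any(dt <= 0)) msgs <- c(msgs, "time must be strictly increasing")
  else {
    med <- stats::median(dt)
    if (max(abs(dt - med)) > .GRID_RTOL * med)
      msgs <- c(msgs, "time grid is not uniform within 1e-6")
  }
  n <- length(t)
  if (!length(object@channels)) msgs <- c(msgs, "at least one channel required")
  if (!all(vapply(object@channels, length, 0L) == n))
    msgs <- c(msgs, "all channels must have the same length as time")
  if (any(!vapply(object@channels, function(x) all(is.finite(x)), TRUE)))
    msgs <- c(msgs, "channel values must be finite")
  if (!object@modality %in% c("ratiometric", "single"))
    msgs <- c(msgs, "modality must be 'ratiometric' or 'single'")
  if (object@modality == "ratiometric" &&
      !all(c("F340", "F380") %in% names(object@channels)))
    msgs <- c(msgs, "ratiometric traces need channels F340 and F380")
  if (object@modality == "single" && !"F" %in% names(object@channels))
    msgs <- c(msgs, "single-channel traces need channel F")
  # sampling_rate * span = n - 1 within rounding
  if (abs(object@samplingRate * (t[n] - t[1]) - (n - 1)) > 0.5)
    msgs <- c(msgs, "samplingRate inconsistent with time span")
  if (length(object@stimTimes) &&
      (min(object@stimTimes) < t[1] - 1e-9 || max(object@stimTimes) > t[n] + 1e-9))
    msgs <- c(msgs, "stimTimes must lie within the recording")
  if (length(msgs)) msgs else TRUE
})

#' RatioTrace: analysis-ready ratio or dF/F0 signal
#'
#' A derived, dimensionless signal: the 340/380 Fura-2 ratio
#' (\code{kind = "ratio"}) or the baseline-normalised fluorescence change
#' \code{(F - F0)/F0} (\code{kind = "dff"}). Stimulation/event metadata are
#' carried over from the source trace.
#'
#' @slot time numeric, seconds.
#' @slot signal numeric, dimensionless.
#' @slot kind \code{"ratio"} or \code{"dff"}.
#' @slot f0 numeric, baseline used (a.u.); \code{NA} for ratio traces.
#' @slot provenance character, id of the source trace.
#' @slot stimFreq,stimTimes,events as in \linkS4class{FluorescenceTrace}.
#'
#' @exportClass RatioTrace
setClass("RatioTrace",
  representation(time = "numeric", signal = "numeric", kind = "character",
                 f0 = "numeric", provenance = "character",
                 stimFreq = "numeric", stimTimes = "numeric",
                 events = "data.frame"))

setValidity("RatioTrace", function(object) {
  msgs <- character(0)
  if (length(object@signal) != length(object@time))
    msgs <- c(msgs, "signal and time must have the same length")
  if (!all(is.finite(object@signal)))
    msgs <- c(msgs, "signal must be finite everywhere")
  if (!object@kind %in% c("ratio", "dff"))
    msgs <- c(msgs, "kind must be 'ratio' or 'dff'")
  if (object@kind == "dff" && !(is.finite(object@f0) && object@f0 > 0))
    msgs <- c(msgs, "f0 must be > 0 for dff traces")
  if (length(msgs)) msgs else TRUE
})

#' OxygraphRecording: event-marked respirometry time series
#'
#' Oxygen concentration and safranine-O fluorescence recorded in one
#' respirometer chamber, with the titration protocol encoded as ordered
#' events (\code{GMP}, \code{ADP_HEX}, \code{CACL2}, \code{FCCP}).
#'
#' @slot time numeric, seconds.
#' @slot o2 numeric, oxygen concentration in uM.
#' @slot safranine numeric, safranine-O concentration-equivalent signal (uM).
#' @slot events data.frame with columns \code{label}, \code{time} and
#'   optionally \code{dose} (cumulative CaCl2 additions, mM).
#' @slot chamberVolume numeric, chamber volume in mL.
#' @slot tissueMass numeric, tissue mass in the chamber, mg.
#' @slot freeCaLadder data.frame mapping cumulative CaCl2 (mM, column
#'   \code{cacl2_mM}) to free calcium (uM, column \code{free_ca_uM});
#'   supplied externally (speciation is not computed here).
#'
#' @exportClass OxygraphRecording
setClass("OxygraphRecording",
  representation(time = "numeric", o2 = "numeric", safranine = "numeric",
                 events = "data.frame", chamberVolume = "numeric",
                 tissueMass = "numeric", freeCaLadder = "data.frame"))

setValidity("OxygraphRecording", function(object) {
  msgs <- character(0)
  n <- length(object@time)
  if (length(object@o2) != n || length(object@safranine) != n)
    msgs <- c(msgs, "o2 and safranine must match time length")
  if (any(diff(object@time) <= 0)) msgs <- c(msgs, "time must be strictly increasing")
  if (any(object@o2 < 0)) msgs <- c(msgs, "o2 concentration must be >= 0")
  if (!(object@chamberVolume > 0)) msgs <- c(msgs, "chamberVolume must be > 0")
  if (!(object@tissueMass > 0)) msgs <- c(msgs, "tissueMass must be > 0")
  ev <- object@events
  if (nrow(ev)) {
    if (!all(ev$label %in% .EVENT_LABELS_OXY))
      msgs <- c(msgs, sprintf("unknown event label; allowed: %s",
                              paste(.EVENT_LABELS_OXY, collapse = ", ")))
    if (is.unsorted(ev$time, strictly = TRUE))
      msgs <- c(msgs, "events must be in strictly increasing time order")
  }
  if (length(msgs)) msgs else TRUE
})

#' LabelImage: a 2-D intensity image with physical pixel size
#'
#' @slot pixels numeric matrix of intensities (rows = image rows, pixel
#'   (1,1) at the top-left; physical x runs along columns, y along rows).
#' @slot pixelSize numeric, pixel edge length in nm.
#' @slot channelLabel one of \code{TOM20}, \code{RyR2}, \code{phalloidin},
#'   \code{unknown}.
#' @slot frame numeric length-2, physical extent (x, y) in um.
#'
#' @exportClass LabelImage
setClass("LabelImage",
  representation(pixels = "matrix", pixelSize = "numeric",
                 channelLabel = "character", frame = "numeric"))

setValidity("LabelImage", function(object) {
  msgs <- character(0)
  if (!(object@pixelSize > 0)) msgs <- c(msgs, "pixelSize must be > 0")
  if (!object@channelLabel %in% .CHANNEL_LABELS)
    msgs <- c(msgs, sprintf("channelLabel must be one of: %s",
                            paste(.CHANNEL_LABELS, collapse = ", ")))
  px_um <- object@pixelSize / 1000
  want <- c(ncol(object@pixels), nrow(object@pixels)) * px_um
  if (length(object@frame) != 2L || any(abs(object@frame - want) > px_um))
    msgs <- c(msgs, "frame must equal image shape x pixel size (within one pixel)")
  if (length(msgs)) msgs else TRUE
})

#' PsiCalibration: constants for safranine-O Nernst conversion
#'
#' Every symbol of the membrane-potential calculation: the total safranine-O
#' added (\code{cTotal}), the residual extramitochondrial concentration after
#' uncoupling (\code{cFCCP}, which also absorbs non-mitochondrial uptake),
#' buffer and mitochondrial volumes, temperature and physical constants.
#'
#' @slot cTotal numeric, uM safranine-O added (2 uM in the assay).
#' @slot cFCCP numeric, uM safranine signal after FCCP; \code{NA} to estimate
#'   it from the FCCP state of a recording.
#' @slot vRB numeric, respiration-buffer volume, mL.
#' @slot vMito numeric, mitochondrial volume, uL (3.1 uL/mg x tissue mass).
#' @slot temperature numeric, K.
#' @slot z numeric, valence of safranine-O (+1).
#' @slot gasConstant numeric, J/(mol K).
#' @slot faraday numeric, C/mol.
#'
#' @exportClass PsiCalibration
setClass("PsiCalibration",
  representation(cTotal = "numeric", cFCCP = "numeric", vRB = "numeric",
                 vMito = "numeric", temperature = "numeric", z = "numeric",
                 gasConstant = "numeric", faraday = "numeric"))

setValidity("PsiCalibration", function(object) {
  msgs <- character(0)
  if (!(object@vRB > 0)) msgs <- c(msgs, "vRB must be > 0")
  if (!(object@vMito > 0)) msgs <- c(msgs, "vMito must be > 0")
  if (!(object@temperature > 0)) msgs <- c(msgs, "temperature must be > 0")
  if (is.finite(object@cFCCP) &&
      !(object@cFCCP > 0 && object@cFCCP <= object@cTotal))
    msgs <- c(msgs, "cFCCP must satisfy 0 < cFCCP <= cTotal")
  if (length(msgs)) msgs else TRUE
})

#' ClusterSet: segmented label clusters
#'
#' @slot clusters data.frame with one row per cluster: \code{id},
#'   \code{n_pixels}, \code{area_um2}, \code{x_um}, \code{y_um} (centroid),
#'   \code{edge} (touches the frame border).
#' @slot source character, image id.
#' @slot channelLabel character.
#' @slot thresholdUsed numeric intensity threshold actually applied.
#' @slot thresholdMethod character ("otsu" or "fixed"), kept for provenance.
#' @slot minSize integer, minimum pixel count retained.
#' @slot pixelSize numeric, nm.
#' @slot frame numeric length-2, um.
#'
#' @exportClass ClusterSet
setClass("ClusterSet",
  representation(clusters = "data.frame", source = "character",
                 channelLabel = "character", thresholdUsed = "numeric",
                 thresholdMethod = "character", minSize = "integer",
                 pixelSize = "numeric", frame = "numeric"))

setValidity("ClusterSet", function(object) {
  msgs <- character(0)
  cl <- object@clusters
  need <- c("id", "n_pixels", "area_um2", "x_um", "y_um", "edge")
  if (!all(need %in% names(cl)))
    msgs <- c(msgs, paste("clusters must have columns:", paste(need, collapse = ", ")))
  else if (nrow(cl)) {
    px_area <- (object@pixelSize / 1000)^2
    if (max(abs(cl$area_um2 - cl$n_pixels * px_area)) > 1e-9)
      msgs <- c(msgs, "area_um2 must equal n_pixels x pixelSize^2 exactly")
    if (any(cl$x_um < 0 | cl$x_um > object@frame[1] |
            cl$y_um < 0 | cl$y_um > object@frame[2]))
      msgs <- c(msgs, "centroids must lie inside the frame")
  }
  if (length(msgs)) msgs else TRUE
})
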