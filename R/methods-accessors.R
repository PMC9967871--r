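#' Accessors for cardioflux data classes
#'
#' Slot accessors for \linkS4class{FluorescenceTrace},
#' \linkS4class{RatioTrace}, \linkS4class{OxygraphRecording},
#' \linkS4class{LabelImage} and \linkS4class{ClusterSet}. Prefer these over
#' direct slot access.
#'
#' @param x a cardioflux data object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
setMethod("samplingRate", "FluorescenceTrace", function(x) x@samplingRate)
#' @rdname accessors
setMethod("modality", "FluorescenceTrace", function(x) x@modality)
#' @rdname accessors
setMethod("channelNames", "FluorescenceTrace", function(x) names(x@channels))
#' @rdname accessors
setMethod("traceTime", "FluorescenceTrace", function(x) x@time)
#' @rdname accessors
setMethod("traceTime", "RatioTrace", function(x) x@time)
#' @rdname accessors
setMethod("traceTime", "OxygraphRecording", function(x) x@time)
#' @rdname accessors
setMethod("signalValues", "RatioTrace", function(x) x@signal)
#' @rdname accessors
setMethod("stimFrequency", "FluorescenceTrace", function(x) x@stimFreq)
#' @rdname accessors
setMethod("stimFrequency", "RatioTrace", function(x) x@stimFreq)
#' @rdname accessors
setMethod("stimTimes", "FluorescenceTrace", function(x) x@stimTimes)
#' @rdname accessors
setMethod("stimTimes", "RatioTrace", function(x) x@stimTimes)
#' @rdname accessors
setMethod("traceEvents", "FluorescenceTrace", function(x) x@events)
#' @rdname accessors
setMethod("traceEvents", "RatioTrace", function(x) x@events)
#' @rdname accessors
setMethod("traceEvents", "OxygraphRecording", function(x) x@events)
#' @rdname accessors
setMethod("o2Concentration", "OxygraphRecording", function(x) x@o2)
#' @rdname accessors
setMethod("safranine", "OxygraphRecording", function(x) x@safranine)
#' @rdname accessors
setMethod("chamberVolume", "OxygraphRecording", function(x) x@chamberVolume)
#' @rdname accessors
setMethod("tissueMass", "OxygraphRecording", function(x) x@tissueMass)
#' @rdname accessors
setMethod("pixelSize", "LabelImage", function(x) x@pixelSize)
#' @rdname accessors
setMethod("pixelSize", "ClusterSet", function(x) x@pixelSize)
#' @rdname accessors
setMethod("frameSize", "LabelImage", function(x) x@frame)
#' @rdname accessors
setMethod("frameSize", "ClusterSet", function(x) x@frame)
#' @rdname accessors
setMethod("imagePixels", "LabelImage", function(x) x@pixels)
#' @rdname accessors
setMethod("channelLabel", "LabelImage", function(x) x@channelLabel)
#' @rdname accessors
setMethod("channelLabel", "ClusterSet", function(x) x@channelLabel)
#' @rdname accessors
setMethod("clusters", "ClusterSet", function(x) x@clusters)
#' @rdname accessors
setMethod("nClusters", "ClusterSet", function(x) nrow(x@clusters))

#' @export
setMethod("show", "FluorescenceTrace", function(object) {
  t <- object@time
  cat(sprintf("FluorescenceTrace (%s): %d samples, %.4g s at %.6g Hz\n",
              object@modality, length(t), t[length(t)] - t[1], object@samplingRate))
  cat(sprintf("  channels: %s\n", paste(names(object@channels), collapse = ", ")))
  if (object@stimFreq > 0) cat(sprintf("  paced at %.3g Hz\n", object@stimFreq))
  if (length(object@stimTimes)) cat(sprintf("  %d explicit stimulus times\n",
                                            length(object@stimTimes)))
  if (nrow(object@events))
    cat(sprintf("  events: %s\n",
                paste(sprintf("%s@%.3gs", object@events$label, object@events$time),
                      collapse = ", ")))
  invisible(NULL)
})

#' @export
setMethod("show", "RatioTrace", function(object) {
  cat(sprintf("RatioTrace (%s): %d samples, range [%.4g, %.4g]\n",
              object@kind, length(object@signal),
              min(object@signal), max(object@signal)))
  if (object@kind == "dff") cat(sprintf("  f0 = %.6g a.u.\n", object@f0))
  invisible(NULL)
})

#' @export
setMethod("show", "OxygraphRecording", function(object) {
  cat(sprintf("OxygraphRecording: %d samples over %.5g s\n",
              length(object@time), diff(range(object@time))))
  cat(sprintf("  chamber %.3g mL, tissue %.3g mg\n",
              object@chamberVolume, object@tissueMass))
  if (nrow(object@events))
    cat(sprintf("  events: %s\n",
                paste(sprintf("%s@%.4gs", object@events$label, object@events$time),
                      collapse = " -> ")))
  invisible(NULL)
})

#' @export
setMethod("show", "LabelImage", function(object) {
  cat(sprintf("LabelImage [%s]: %d x %d px at %.3g nm -> %.4g x %.4g um\n",
              object@channelLabel, nrow(object@pixels), ncol(object@pixels),
              object@pixelSize, object@frame[1], object@frame[2]))
  invisible(NULL)
})

#' @export
setMethod("show", "ClusterSet", function(object) {
  cat(sprintf("ClusterSet [%s]: %d clusters (threshold %.4g, %s; min size %d px)\n",
              object@channelLabel, nrow(object@clusters), object@thresholdUsed,
              object@thresholdMethod, object@minSize))
  if (nrow(object@clusters))
    cat(sprintf("  mean area %.4g um^2 over %.3g x %.3g um frame\n",
                mean(object@clusters$area_um2), object@frame[1], object@frame[2]))
  invisible(NULL)
})
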