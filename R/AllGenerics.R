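#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("traceTime", function(x) standardGeneric("traceTime"))
#' @rdname accessors
#' @export
setGeneric("signalValues", function(x) standardGeneric("signalValues"))
#' @rdname accessors
#' @export
setGeneric("stimFrequency", function(x) standardGeneric("stimFrequency"))
#' @rdname accessors
#' @export
setGeneric("stimTimes", function(x) standardGeneric("stimTimes"))
#' @rdname accessors
#' @export
setGeneric("traceEvents", function(x) standardGeneric("traceEvents"))
#' @rdname accessors
#' @export
setGeneric("o2Concentration", function(x) standardGeneric("o2Concentration"))
#' @rdname accessors
#' @export
setGeneric("safranine", function(x) standardGeneric("safranine"))
#' @rdname accessors
#' @export
setGeneric("chamberVolume", function(x) standardGeneric("chamberVolume"))
#' @rdname accessors
#' @export
setGeneric("tissueMass", function(x) standardGeneric("tissueMass"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("frameSize", function(x) standardGeneric("frameSize"))
#' @rdname accessors
#' @export
setGeneric("imagePixels", function(x) standardGeneric("imagePixels"))
#' @rdname accessors
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))
#' @rdname accessors
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))
#' @rdname accessors
#' @export
setGeneric("channelLabel", function(x) standardGeneric("channelLabel"))
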