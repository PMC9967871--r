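#' Construct a FluorescenceTrace
#'
#' @param time numeric vector of sample times (s), uniform grid.
#' @param channels named list of intensity vectors; \code{F340}/\code{F380}
#'   for ratiometric recordings, \code{F} for single-channel ones.
#' @param samplingRate Hz; inferred from the median time step when missing.
#' @param modality \code{"ratiometric"} or \code{"single"}; inferred from the
#'   channel names when missing.
#' @param stimFreq pacing frequency, Hz (0 = unpaced).
#' @param stimTimes optional explicit stimulus times, s.
#' @param events data.frame with columns \code{label}, \code{time}.
#' @param meta list of metadata (cell id, group, condition).
#' @return A validated \linkS4class{FluorescenceTrace}.
#' @export
FluorescenceTrace <- function(time, channels, samplingRate = NULL,
                              modality = NULL, stimFreq = 0,
                              stimTimes = numeric(0), events = emptyEvents(),
                              meta = list()) {
  dt <- checkUniformGrid(time)
  if (is.null(samplingRate)) samplingRate <- 1 / dt
  if (is.null(modality))
    modality <- if (all(c("F340", "F380") %in% names(channels)))
      "ratiometric" else "single"
  if (any(!vapply(channels, function(x) all(is.finite(x)), TRUE)))
    cfStop("non-finite channel values are rejected at construction",
           "cardioflux_io_error")
  new("FluorescenceTrace", time = as.numeric(time),
      channels = lapply(channels, as.numeric),
      samplingRate = samplingRate, modality = modality,
      stimFreq = stimFreq, stimTimes = as.numeric(stimTimes),
      events = events, meta = meta)
}

#' Read a fluorescence trace from delimited text
#'
#' Expects a CSV with a header row, a \code{time_s} column and either both
#' \code{F340} and \code{F380} columns (ratiometric) or a single \code{F}
#' column. A JSON sidecar sharing the basename (\code{foo.json} next to
#' \code{foo.csv}) may supply \code{stim_freq}, \code{stim_times},
#' \code{events} (list of \code{{label, time}}) and \code{meta}.
#'
#' @param path CSV file path.
#' @param schema optional named character vector mapping the expected column
#'   names to the names actually present, e.g.
#'   \code{c(time_s = "t", F = "fluo")}.
#' @return A \linkS4class{FluorescenceTrace}; the sampling rate is inferred
#'   from the median time step.
#' @export
readTrace <- function(path, schema = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!is.null(schema))
    for (want in names(schema)) {
      have <- schema[[want]]
      if (!have %in% names(df))
        cfStop(sprintf("missing required column '%s' (mapped from '%s')", have, want),
               "cardioflux_io_error")
      names(df)[names(df) == have] <- want
    }
  if (!"time_s" %in% names(df))
    cfStop("missing required column 'time_s'", "cardioflux_io_error")
  chan_names <- intersect(c("F340", "F380", "F"), names(df))
  if (!length(chan_names))
    cfStop("missing intensity columns: need F340+F380 or F", "cardioflux_io_error")
  if (("F340" %in% chan_names) != ("F380" %in% chan_names))
    cfStop(sprintf("missing required column '%s'",
                   setdiff(c("F340", "F380"), chan_names)), "cardioflux_io_error")
  if (any(!is.finite(as.matrix(df[chan_names]))))
    cfStop("non-finite samples in intensity columns", "cardioflux_io_error")
  checkUniformGrid(df$time_s)
  sc <- readSidecar(path)
  ev <- emptyEvents()
  if (!is.null(sc$events) && length(sc$events))
    ev <- data.frame(label = as.character(sc$events$label),
                     time = as.numeric(sc$events$time), stringsAsFactors = FALSE)
  FluorescenceTrace(
    time = df$time_s, channels = as.list(df[chan_names]),
    stimFreq = if (!is.null(sc$stim_freq)) sc$stim_freq else 0,
    stimTimes = if (!is.null(sc$stim_times)) as.numeric(sc$stim_times) else numeric(0),
    events = ev,
    meta = if (!is.null(sc$meta)) as.list(sc$meta) else list())
}

#' Write a fluorescence trace to CSV plus JSON sidecar
#'
#' Inverse of \code{\link{readTrace}}: values round-trip to better than 1e-9
#' relative.
#'
#' @param trace a \linkS4class{FluorescenceTrace}.
#' @param path output CSV path; the sidecar is written next to it.
#' @return \code{path}, invisibly.
#' @export
writeTrace <- function(trace, path) {
  df <- data.frame(time_s = trace@time, check.names = FALSE)
  for (nm in names(trace@channels)) df[[nm]] <- trace@channels[[nm]]
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  sc <- list(stim_freq = trace@stimFreq, meta = trace@meta)
  if (length(trace@stimTimes)) sc$stim_times <- trace@stimTimes
  if (nrow(trace@events)) sc$events <- trace@events
  jsonlite::write_json(sc, jsonSidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Compute the 340/380 excitation ratio
#'
#' Pointwise ratio of the two Fura-2 excitation channels. The ratio cancels
#' dye concentration and path length, so it is invariant under joint positive
#' scaling of both channels.
#'
#' @param trace a ratiometric \linkS4class{FluorescenceTrace}.
#' @return A \linkS4class{RatioTrace} with \code{kind = "ratio"}.
#' @export
computeRatio <- function(trace) {
  stopifnot(is(trace, "FluorescenceTrace"))
  if (trace@modality != "ratiometric")
    cfStop("computeRatio needs a ratiometric trace", "cardioflux_signal_error")
  f380 <- trace@channels$F380
  bad <- which(f380 <= 0)
  if (length(bad))
    cfStop(sprintf("F380 <= 0 at sample index %d", bad[1]), "cardioflux_signal_error")
  new("RatioTrace", time = trace@time, signal = trace@channels$F340 / f380,
      kind = "ratio", f0 = NA_real_,
      provenance = if (!is.null(trace@meta$id)) as.character(trace@meta$id) else "",
      stimFreq = trace@stimFreq, stimTimes = trace@stimTimes,
      events = trace@events)
}

#' Compute dF/F0 from a single-channel trace
#'
#' \code{F0} is the mean fluorescence over a baseline window (half-open,
#' \code{[t_start, t_end)}); the signal is \code{(F - F0)/F0}. This is the
#' amplitude scale used for mitochondrial (Rhod-2) transients.
#'
#' @param trace a single-channel \linkS4class{FluorescenceTrace}.
#' @param f0_window numeric length-2, baseline window in seconds; must lie
#'   inside the recording and contain at least 10 samples.
#' @param background optional constant background to subtract from the
#'   channel before normalising (default 0).
#' @return A \linkS4class{RatioTrace} with \code{kind = "dff"}.
#' @export
computeDff <- function(trace, f0_window, background = 0) {
  stopifnot(is(trace, "FluorescenceTrace"))
  if (trace@modality != "single")
    cfStop("computeDff needs a single-channel trace", "cardioflux_signal_error")
  t <- trace@time
  if (f0_window[1] < t[1] - 1e-9 || f0_window[2] > t[length(t)] + 1e-9)
    cfStop("f0 window lies outside the recording", "cardioflux_signal_error")
  sel <- inWindow(t, f0_window[1], f0_window[2])
  if (sum(sel) < 10L)
    cfStop("f0 window must contain at least 10 samples", "cardioflux_signal_error")
  f <- trace@channels$F - background
  f0 <- mean(f[sel])
  if (f0 <= 0) cfStop("f0 must be > 0", "cardioflux_signal_error")
  new("RatioTrace", time = t, signal = (f - f0) / f0, kind = "dff", f0 = f0,
      provenance = if (!is.null(trace@meta$id)) as.character(trace@meta$id) else "",
      stimFreq = trace@stimFreq, stimTimes = trace@stimTimes,
      events = trace@events)
}

#' Construct a RatioTrace directly
#'
#' Low-level constructor wrapping an arbitrary dimensionless signal (already
#' a ratio or dF/F0) as a \linkS4class{RatioTrace}; normally these objects
#' come from \code{\link{computeRatio}} / \code{\link{computeDff}}.
#'
#' @param time,signal numeric vectors of equal length.
#' @param kind \code{"ratio"} or \code{"dff"}.
#' @param f0 baseline (required > 0 for dff).
#' @param stimFreq,stimTimes,events stimulation/event metadata.
#' @param provenance source trace id.
#' @return A validated \linkS4class{RatioTrace}.
#' @export
RatioTrace <- function(time, signal, kind = "ratio", f0 = NA_real_,
                       stimFreq = 0, stimTimes = numeric(0),
                       events = emptyEvents(), provenance = "") {
  new("RatioTrace", time = as.numeric(time), signal = as.numeric(signal),
      kind = kind, f0 = f0, provenance = provenance, stimFreq = stimFreq,
      stimTimes = as.numeric(stimTimes), events = events)
}

makeRatioTrace <- RatioTrace
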