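# Internal helpers shared across modules.

# Structured error: all user-facing failures carry class "cardioflux_error"
# plus a specific subclass, so callers can branch on condition classes.
cfStop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cardioflux_error", "error", "condition")))
}

cfWarn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "cardioflux_warning", "warning", "condition")))
}

# Relative tolerance on time-grid uniformity: 1 part in 1e6 of the median step.
.GRID_RTOL <- 1e-6

checkUniformGrid <- function(time, what = "time") {
  if (length(time) < 2L) cfStop(sprintf("%s grid needs at least 2 samples", what),
                                "cardioflux_grid_error")
  dt <- diff(time)
  if (any(dt <= 0)) cfStop("non-uniform time grid: time must be strictly increasing",
                           "cardioflux_grid_error")
  med <- stats::median(dt)
  if (max(abs(dt - med)) > .GRID_RTOL * med)
    cfStop("non-uniform time grid", "cardioflux_grid_error")
  invisible(med)
}

# Centered moving average with shrinking windows at the edges, so the output
# has the same length as the input and no NA padding.
movingAverage <- function(x, width) {
  width <- as.integer(width)
  if (width <= 1L) return(x)
  n <- length(x)
  h <- width %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Half-open window selector on a time vector.
inWindow <- function(time, t_start, t_end) time >= t_start & time < t_end

# Deterministic per-task RNG seed derived from a base seed; keeps every
# generator a pure function of (spec, seed) without touching global state.
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) cfStop("a seed is required", "cardioflux_seed_error")
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Combine a base seed with a small offset, staying inside 32-bit range.
deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k) %% 2147483587)
}

sem <- function(x) stats::sd(x) / sqrt(length(x))

jsonSidecarPath <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

readSidecar <- function(path) {
  sc <- jsonSidecarPath(path)
  if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE) else NULL
}
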