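#' Construct an OxygraphRecording
#'
#' @param time seconds. @param o2 oxygen concentration, uM.
#' @param safranine safranine-O signal, uM-equivalent.
#' @param events data.frame with \code{label} (one of GMP, ADP_HEX, CACL2,
#'   FCCP), \code{time} (s) and optionally \code{dose} (mM CaCl2 added).
#' @param chamberVolume chamber volume, mL. @param tissueMass tissue, mg.
#' @param freeCaLadder data.frame mapping cumulative CaCl2 (\code{cacl2_mM})
#'   to free calcium (\code{free_ca_uM}); see
#'   \code{system.file("extdata", "free_ca_ladder.json", package = "cardioflux")}
#'   for the shipped example.
#' @return A validated \linkS4class{OxygraphRecording}.
#' @export
OxygraphRecording <- function(time, o2, safranine, events = NULL,
                              chamberVolume = 2, tissueMass = 2,
                              freeCaLadder = NULL) {
  if (is.null(events))
    events <- data.frame(label = character(0), time = numeric(0),
                         dose = numeric(0), stringsAsFactors = FALSE)
  if (!"dose" %in% names(events)) events$dose <- NA_real_
  if (is.null(freeCaLadder))
    freeCaLadder <- data.frame(cacl2_mM = numeric(0), free_ca_uM = numeric(0))
  new("OxygraphRecording", time = as.numeric(time), o2 = as.numeric(o2),
      safranine = as.numeric(safranine), events = events,
      chamberVolume = chamberVolume, tissueMass = tissueMass,
      freeCaLadder = freeCaLadder)
}

#' Read an oxygraph recording from delimited text
#'
#' Expects CSV columns \code{time_s}, \code{o2_uM}, \code{safranine_uM} and
#' \code{event} (empty string except at event samples; allowed labels GMP,
#' ADP_HEX, CACL2, FCCP). An optional \code{event_dose_mM} column carries the
#' CaCl2 dose of each titration. Chamber volume, tissue mass and the free-Ca
#' ladder come from the JSON sidecar or from the arguments (arguments win).
#'
#' @param path CSV path.
#' @param chamberVolume,tissueMass,freeCaLadder overrides for the sidecar.
#' @return An \linkS4class{OxygraphRecording}.
#' @export
readOxygraph <- function(path, chamberVolume = NULL, tissueMass = NULL,
                         freeCaLadder = NULL) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(event = "character"))
  need <- c("time_s", "o2_uM", "safranine_uM", "event")
  miss <- setdiff(need, names(df))
  if (length(miss))
    cfStop(sprintf("missing required column '%s'", miss[1]), "cardioflux_io_error")
  evi <- which(!is.na(df$event) & nzchar(df$event))
  if (length(evi)) {
    bad <- setdiff(unique(df$event[evi]), .EVENT_LABELS_OXY)
    if (length(bad))
      cfStop(sprintf("unknown event label '%s'; allowed: %s", bad[1],
                     paste(.EVENT_LABELS_OXY, collapse = ", ")),
             "cardioflux_io_error")
  }
  events <- data.frame(label = df$event[evi], time = df$time_s[evi],
                       dose = if ("event_dose_mM" %in% names(df))
                         df$event_dose_mM[evi] else NA_real_,
                       stringsAsFactors = FALSE)
  sc <- readSidecar(path)
  if (is.null(chamberVolume))
    chamberVolume <- if (!is.null(sc$chamber_volume_ml)) sc$chamber_volume_ml else 2
  if (is.null(tissueMass))
    tissueMass <- if (!is.null(sc$tissue_mass_mg)) sc$tissue_mass_mg else 2
  if (is.null(freeCaLadder) && !is.null(sc$free_ca_ladder))
    freeCaLadder <- as.data.frame(sc$free_ca_ladder)
  OxygraphRecording(df$time_s, df$o2_uM, df$safranine_uM, events,
                    chamberVolume, tissueMass, freeCaLadder)
}

#' Write an oxygraph recording to CSV plus JSON sidecar
#' @param rec an \linkS4class{OxygraphRecording}. @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeOxygraph <- function(rec, path) {
  ev <- rep("", length(rec@time))
  dose <- rep(NA_real_, length(rec@time))
  if (nrow(rec@events)) {
    idx <- vapply(rec@events$time, function(tt) which.min(abs(rec@time - tt)), 0L)
    ev[idx] <- rec@events$label
    dose[idx] <- rec@events$dose
  }
  df <- data.frame(time_s = rec@time, o2_uM = rec@o2,
                   safranine_uM = rec@safranine, event = ev,
                   event_dose_mM = dose, check.names = FALSE)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE,
                                                scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  sc <- list(chamber_volume_ml = rec@chamberVolume,
             tissue_mass_mg = rec@tissueMass)
  if (nrow(rec@freeCaLadder)) sc$free_ca_ladder <- rec@freeCaLadder
  jsonlite::write_json(sc, jsonSidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
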