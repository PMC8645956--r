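# Ventilator waveform container and CSV I/O.

#' Construct a ventilator waveform recording
#'
#' A `waveform_recording` holds synchronized airway pressure, flow and
#' (optionally) esophageal pressure sampled on a uniform time grid, plus
#' study metadata. All mechanics and power computations start from this
#' object.
#'
#' @param time Time in seconds, strictly increasing, uniform grid.
#' @param paw Airway pressure, cmH2O.
#' @param flow Air flow, L/s, inspiration positive.
#' @param peso Optional esophageal pressure, cmH2O.
#' @param sample_rate Sampling rate in Hz. Inferred from `time` when `NULL`.
#' @param meta Named list of metadata: `animal`, `timepoint`,
#'   `peep_set_cmh2o`, `rr_set`, `body_mass_kg` are recognized downstream.
#'
#' @return An object of class `waveform_recording`.
#' @export
waveform_recording <- function(time, paw, flow, peso = NULL,
                               sample_rate = NULL, meta = list()) {
  n <- length(time)
  if (n < 2L)
    .stop_data("waveform_recording: need at least 2 samples, got %d", n)
  if (length(paw) != n || length(flow) != n)
    .stop_data("waveform_recording: channel lengths differ (time %d, paw %d, flow %d)",
               n, length(paw), length(flow))
  if (!is.null(peso) && length(peso) != n)
    .stop_data("waveform_recording: peso length %d != %d", length(peso), n)
  dt <- diff(time)
  if (any(dt <= 0))
    .stop_data("waveform_recording: time must be strictly increasing")
  if (is.null(sample_rate)) sample_rate <- 1 / stats::median(dt)
  if (!.is_count(sample_rate))
    .stop_data("waveform_recording: sample_rate must be a positive number")
  if (any(abs(dt - 1 / sample_rate) > 1e-6))
    .stop_data("waveform_recording: time grid inconsistent with sample_rate %.6g Hz",
               sample_rate)
  structure(list(time = as.numeric(time), paw = as.numeric(paw),
                 flow = as.numeric(flow),
                 peso = if (is.null(peso)) NULL else as.numeric(peso),
                 sample_rate = as.numeric(sample_rate), meta = meta),
            class = "waveform_recording")
}

#' @export
print.waveform_recording <- function(x, ...) {
  cat(sprintf("waveform_recording: %d samples @ %.6g Hz (%.2f s)%s\n",
              length(x$time), x$sample_rate,
              x$time[length(x$time)] - x$time[1],
              if (is.null(x$peso)) "" else ", with esophageal channel"))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' Column mapping for waveform CSV files
#'
#' @param time,paw,flow,peso Column names in the CSV file.
#' @param flow_unit `"L/s"` or `"L/min"`; flow is converted to L/s on read.
#'
#' @return A named list used by [read_waveform()].
#' @export
waveform_config <- function(time = "time_s", paw = "paw_cmH2O",
                            flow = "flow_Lps", peso = "peso_cmH2O",
                            flow_unit = c("L/s", "L/min")) {
  list(time = time, paw = paw, flow = flow, peso = peso,
       flow_unit = match.arg(flow_unit))
}

#' Read a ventilator waveform CSV
#'
#' Expects a header row naming the time, airway-pressure and flow columns
#' (esophageal pressure optional). Flow recorded in L/min is converted to
#' L/s.
#'
#' @param path Path to a CSV file.
#' @param config Channel map from [waveform_config()].
#' @param meta Metadata list attached to the recording.
#'
#' @return A [waveform_recording()].
#' @export
read_waveform <- function(path, config = waveform_config(), meta = list()) {
  df <- utils::read.csv(path, check.names = FALSE)
  for (ch in c("time", "paw", "flow")) {
    if (!(config[[ch]] %in% names(df)))
      .stop_data("read_waveform: required column '%s' (%s) missing in %s",
                 config[[ch]], ch, path)
  }
  if (nrow(df) < 2L)
    .stop_data("read_waveform: %s has %d row(s); need at least 2", path, nrow(df))
  time <- df[[config$time]]
  if (any(diff(time) <= 0))
    .stop_data("read_waveform: non-monotone time column in %s", path)
  flow <- df[[config$flow]]
  if (config$flow_unit == "L/min") flow <- flow / 60
  peso <- if (config$peso %in% names(df)) df[[config$peso]] else NULL
  waveform_recording(time = time, paw = df[[config$paw]], flow = flow,
                     peso = peso, meta = meta)
}

#' Write a ventilator waveform CSV
#'
#' Writes the standard column layout (`time_s, paw_cmH2O, flow_Lps` and
#' `peso_cmH2O` when present) with full double precision, so that a
#' write/read cycle reproduces the recording bit-identically.
#'
#' @param rec A [waveform_recording()].
#' @param path Output file path.
#'
#' @return `path`, invisibly.
#' @export
write_waveform <- function(rec, path) {
  stopifnot(inherits(rec, "waveform_recording"))
  cols <- list(time_s = rec$time, paw_cmH2O = rec$paw, flow_Lps = rec$flow)
  if (!is.null(rec$peso)) cols$peso_cmH2O <- rec$peso
  txt <- vapply(cols, function(v) sprintf("%.17g", v), character(length(rec$time)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(cols), collapse = ","), con)
  writeLines(apply(txt, 1L, paste, collapse = ","), con)
  invisible(path)
}
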