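# Breath segmentation and volume integration.

.breath <- function(onset, insp_end, end, pause, fs) {
  stopifnot(onset < insp_end, insp_end <= end)
  structure(list(onset = onset, insp_end = insp_end, end = end,
                 pause = pause,                     # c(start, end) indices or NULL
                 duration = (end - onset) / fs,
                 rr = 60 / ((end - onset) / fs)),
            class = "breath")
}

#' Segment a recording into breaths
#'
#' Breath onsets are detected as upward crossings of the flow signal above
#' a small positive threshold; a crossing only triggers after flow has been
#' non-positive for at least the hysteresis duration (first sample counts
#' as an onset when the recording starts mid-flow). Each breath spans
#' half-open `[onset, next onset)`. The trailing segment after the last
#' onset is kept only when its duration is consistent with the preceding
#' cycles, so a recording truncated mid-inspiration drops its partial
#' breath. Within each breath the inspiration ends where flow first falls
#' below `-threshold`; a zero-flow run immediately before that point is the
#' end-inspiratory pause.
#'
#' @param rec A [waveform_recording()].
#' @param min_duration Minimum breath duration in seconds; shorter
#'   candidates are discarded.
#' @param threshold Flow threshold in L/s for onset detection.
#' @param hysteresis Required non-positive-flow dwell time in seconds
#'   before a new onset can trigger.
#'
#' @return A list of `breath` objects (possibly empty).
#' @export
segment_breaths <- function(rec, min_duration = 0.5, threshold = 0.02,
                            hysteresis = 0.05) {
  stopifnot(inherits(rec, "waveform_recording"))
  f <- rec$flow
  n <- length(f)
  fs <- rec$sample_rate
  arm_run <- max(1L, round(hysteresis * fs))
  cross <- which(f >= threshold & c(-Inf, f[-n]) < threshold)
  if (!length(cross)) return(list())
  onsets <- cross[1L]
  nonpos <- cumsum(f <= 0)
  for (i in cross[-1L]) {
    prev <- onsets[length(onsets)]
    if (nonpos[i] - nonpos[prev] >= arm_run) onsets <- c(onsets, i)
  }
  if (length(onsets) >= 2L) {
    starts <- onsets[-length(onsets)]
    ends <- onsets[-1L]
    cyc <- stats::median((ends - starts) / fs)
    # trailing segment: keep when close to a full cycle
    tail_dur <- (n - onsets[length(onsets)]) / fs
    if (tail_dur >= 0.75 * cyc) {
      starts <- c(starts, onsets[length(onsets)])
      ends <- c(ends, n)
    }
  } else {
    tail_dur <- (n - onsets) / fs
    if (tail_dur < min_duration) return(list())
    starts <- onsets
    ends <- n
  }
  keep <- (ends - starts) / fs >= min_duration
  starts <- starts[keep]; ends <- ends[keep]
  breaths <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    on <- starts[k]; en <- ends[k]
    seg <- f[on:(en - 1L)]
    exp_rel <- which(seg < -threshold)
    insp_end <- if (length(exp_rel)) on + exp_rel[1L] - 1L else en
    pause <- NULL
    j <- insp_end - 1L
    while (j > on && abs(f[j]) <= threshold) j <- j - 1L
    if (j < insp_end - 1L) pause <- c(j + 1L, insp_end - 1L)
    breaths[[k]] <- .breath(on, insp_end, en, pause, fs)
  }
  breaths
}

#' Integrate flow to a per-breath volume trace
#'
#' Cumulative trapezoidal integral of flow over the breath, zeroed at the
#' breath onset (per-breath re-zeroing; no global leak correction). The
#' tidal volume is the maximum of the trace during inspiration.
#'
#' @param rec A [waveform_recording()].
#' @param breath A `breath` from [segment_breaths()].
#'
#' @return Numeric volume trace in litres, one value per sample in
#'   `[onset, end)`, with attribute `vt` (tidal volume, L).
#' @export
integrate_volume <- function(rec, breath) {
  stopifnot(inherits(rec, "waveform_recording"), inherits(breath, "breath"))
  idx <- breath$onset:(breath$end - 1L)
  vol <- .cumtrapz0(rec$time[idx], rec$flow[idx])
  insp <- seq_len(breath$insp_end - breath$onset)
  attr(vol, "vt") <- max(vol[insp])
  vol
}
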