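# Mechanical energy and power from the pressure-volume curve.

.insp_limb <- function(breath) {
  # inspiratory limb: onset through end of pause (start of expiration)
  breath$onset:(breath$insp_end - 1L)
}

#' Mechanical energy of one breath
#'
#' Numerical (trapezoidal) integral of airway pressure over inspired
#' volume along the inspiratory limb of the pressure-volume curve, from
#' breath onset through the end of the inspiratory pause. With
#' `reference = "atmospheric"` the pressure is integrated as recorded
#' (PEEP work included); with `reference = "peep"` the measured PEEP is
#' subtracted first, so the integral covers only the tidal PV loop above
#' PEEP. Result converted with 1 cmH2O.L = 0.0980665 J.
#'
#' @param rec A [waveform_recording()].
#' @param breath A `breath` from [segment_breaths()].
#' @param reference `"atmospheric"` (default) or `"peep"`.
#' @param peep Measured PEEP (cmH2O) used when `reference = "peep"`;
#'   computed via [breath_pressures()] when `NULL`.
#'
#' @return Mechanical energy in joules (single numeric).
#' @export
mechanical_energy <- function(rec, breath,
                              reference = c("atmospheric", "peep"),
                              peep = NULL) {
  reference <- match.arg(reference)
  stopifnot(inherits(rec, "waveform_recording"), inherits(breath, "breath"))
  idx <- breath$onset:(breath$end - 1L)
  vol <- integrate_volume(rec, breath)
  limb <- seq_len(breath$insp_end - breath$onset)
  paw <- rec$paw[idx][limb]
  v <- vol[limb]
  if (any(!is.finite(paw)) || any(!is.finite(v)))
    .stop_data("mechanical_energy: non-finite samples in breath")
  ref <- 0
  if (reference == "peep") {
    if (is.null(peep)) peep <- breath_pressures(rec, breath)$peep
    ref <- peep
  }
  unname(pracma::trapz(v, paw - ref) * .CMH2O_L_TO_J)
}

#' Mechanical power from mechanical energy
#'
#' @param me Mechanical energy per breath, J.
#' @param rr Respiratory rate, 1/min; must be positive.
#'
#' @return Mechanical power in J/min.
#' @export
mechanical_power <- function(me, rr) {
  if (!is.numeric(rr) || any(rr <= 0))
    .stop_data("mechanical_power: rr must be positive")
  me * rr
}

#' Elastic/resistive decomposition of mechanical energy and power
#'
#' The resistive component is the trapezoidal integral of the fitted
#' resistive pressure `R * V'` over inspired volume; the elastic component
#' is defined residually as `ME_total - ME_resistive`, so the
#' decomposition closes exactly. Power components are the energy
#' components times the respiratory rate. Note that with the atmospheric
#' reference the elastic component includes the PEEP-level work.
#'
#' @inheritParams mechanical_energy
#' @param fit An `eom_fit` from [fit_equation_of_motion()] providing the
#'   resistance; `NULL` leaves the components `NA` while the total is
#'   still reported.
#' @param rr Respiratory rate 1/min; defaults to the breath's own rate.
#'
#' @return An object of class `power_result`: list with `me_total`,
#'   `me_elastic`, `me_resistive` (J), `mp_total`, `mp_elastic`,
#'   `mp_resistive` (J/min), `rr`, `reference`.
#' @export
decompose_power <- function(rec, breath, fit = NULL,
                            reference = c("atmospheric", "peep"),
                            peep = NULL, rr = NULL) {
  reference <- match.arg(reference)
  if (is.null(rr)) rr <- breath$rr
  me_total <- mechanical_energy(rec, breath, reference, peep)
  if (is.null(fit)) {
    me_res <- NA_real_
    me_el <- NA_real_
  } else {
    stopifnot(inherits(fit, "eom_fit"))
    idx <- breath$onset:(breath$end - 1L)
    vol <- integrate_volume(rec, breath)
    limb <- seq_len(breath$insp_end - breath$onset)
    me_res <- unname(pracma::trapz(vol[limb],
                                   fit$R * rec$flow[idx][limb]) * .CMH2O_L_TO_J)
    me_el <- me_total - me_res
  }
  structure(list(me_total = me_total, me_elastic = me_el,
                 me_resistive = me_res,
                 mp_total = mechanical_power(me_total, rr),
                 mp_elastic = me_el * rr, mp_resistive = me_res * rr,
                 rr = rr, reference = reference),
            class = "power_result")
}

#' Median mechanical power over breaths
#'
#' @param power A data frame with one row per breath (e.g. from
#'   [analyze_recording()]) containing `mp_total` (and optionally
#'   `mp_elastic`, `mp_resistive`), or a list of `power_result`s.
#' @param window Optional integer index vector selecting breaths.
#'
#' @return Named numeric vector of medians (`mp_total` and available
#'   components).
#' @export
summarize_power <- function(power, window = NULL) {
  if (is.list(power) && !is.data.frame(power) &&
      all(vapply(power, inherits, logical(1), "power_result"))) {
    power <- do.call(rbind, lapply(power, function(p)
      as.data.frame(p[c("mp_total", "mp_elastic", "mp_resistive")])))
  }
  if (!is.null(window)) power <- power[window, , drop = FALSE]
  if (nrow(power) < 1L)
    .stop_data("summarize_power: no breaths in window")
  cols <- intersect(c("mp_total", "mp_elastic", "mp_resistive"), names(power))
  vapply(power[cols], stats::median, numeric(1), na.rm = TRUE)
}

#' Full per-breath analysis of a recording
#'
#' Runs segmentation, pressures, transpulmonary quantities (when an
#' esophageal channel exists), the equation-of-motion fit and the
#' mechanical energy/power decomposition, returning one tidy row per
#' breath.
#'
#' @inheritParams mechanical_energy
#' @param model Equation-of-motion model passed to
#'   [fit_equation_of_motion()].
#' @param min_duration,threshold Passed to [segment_breaths()].
#'
#' @return A data frame, one row per breath: pressures, `vt`, `vt_ml_kg`,
#'   `rr`, fit parameters (`e`, `r`, `pct_e2`, `r_squared`), `me_*` (J)
#'   and `mp_*` (J/min).
#' @export
analyze_recording <- function(rec, model = "volume_dependent",
                              reference = c("atmospheric", "peep"),
                              min_duration = 0.5, threshold = 0.02) {
  reference <- match.arg(reference)
  breaths <- segment_breaths(rec, min_duration = min_duration,
                             threshold = threshold)
  if (!length(breaths)) return(data.frame())
  rows <- lapply(seq_along(breaths), function(k) {
    b <- breaths[[k]]
    mech <- breath_pressures(rec, b)
    mech <- transpulmonary(rec, b, mech)
    fit <- tryCatch(fit_equation_of_motion(rec, b, model = model),
                    error = function(e) NULL)
    pw <- decompose_power(rec, b, fit, reference, peep = mech$peep)
    data.frame(breath = k,
               ppeak = mech$ppeak, pmean = mech$pmean, pplat = mech$pplat,
               peep = mech$peep, dp = mech$dp,
               ptrans_peak = mech$ptrans_peak,
               ptrans_endex = mech$ptrans_endex, dptrans = mech$dptrans,
               vt = mech$vt, vt_ml_kg = mech$vt_ml_kg, rr = mech$rr,
               e = if (is.null(fit)) NA_real_ else fit$E,
               r = if (is.null(fit)) NA_real_ else fit$R,
               pct_e2 = if (is.null(fit)) NA_real_ else fit$pct_e2,
               r_squared = if (is.null(fit)) NA_real_ else fit$r_squared,
               me_total = pw$me_total, me_elastic = pw$me_elastic,
               me_resistive = pw$me_resistive,
               mp_total = pw$mp_total, mp_elastic = pw$mp_elastic,
               mp_resistive = pw$mp_resistive,
               flags = paste(mech$flags, collapse = ";"))
  })
  do.call(rbind, rows)
}
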