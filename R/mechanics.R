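# Per-breath pressures and equation-of-motion fits.

.win_idx <- function(from, to, fs, window) {
  # last `window` seconds of [from, to], as sample indices
  w <- max(1L, round(window * fs))
  seq.int(max(from, to - w + 1L), to)
}

#' Per-breath airway pressures and derived quantities
#'
#' Computes peak and mean airway pressure over the respiratory cycle, the
#' plateau pressure (mean over the last part of the zero-flow
#' end-inspiratory pause), the measured PEEP (mean over the last part of
#' expiration) and the driving pressure `dP = Pplat - PEEP`. When the
#' breath has no zero-flow pause, `pplat` and `dp` are `NA` and flagged.
#'
#' @param rec A [waveform_recording()].
#' @param breath A `breath` from [segment_breaths()].
#' @param pause_window Averaging window (s) at the end of the pause for
#'   `pplat`. Default 0.1 s.
#' @param peep_window Averaging window (s) at the end of expiration for
#'   measured PEEP. Default 0.1 s.
#'
#' @return An object of class `breath_mechanics`: list with `ppeak`,
#'   `pmean`, `pplat`, `peep`, `dp`, `vt`, `vt_ml_kg`, `rr`, and `flags`
#'   (character vector of quality notes, e.g. ordering violations from
#'   noise — flagged, not failed).
#' @export
breath_pressures <- function(rec, breath, pause_window = 0.1,
                             peep_window = 0.1) {
  stopifnot(inherits(rec, "waveform_recording"), inherits(breath, "breath"))
  fs <- rec$sample_rate
  idx <- breath$onset:(breath$end - 1L)
  paw <- rec$paw[idx]
  vol <- integrate_volume(rec, breath)
  flags <- character(0)
  ppeak <- max(paw)
  pmean <- mean(paw)
  if (!is.null(breath$pause)) {
    pw <- .win_idx(breath$pause[1L], breath$pause[2L], fs, pause_window)
    pplat <- mean(rec$paw[pw])
  } else {
    pplat <- NA_real_
    flags <- c(flags, "no_pause")
  }
  ew <- .win_idx(breath$insp_end, breath$end - 1L, fs, peep_window)
  peep <- mean(rec$paw[ew])
  dp <- pplat - peep
  if (!is.na(pplat) && (ppeak < pplat || pplat < peep))
    flags <- c(flags, "pressure_order")
  vt <- attr(vol, "vt")
  if (vt <= 0) flags <- c(flags, "nonpositive_vt")
  mass <- rec$meta$body_mass_kg
  structure(list(ppeak = ppeak, pmean = pmean, pplat = pplat, peep = peep,
                 dp = dp, vt = vt,
                 vt_ml_kg = if (is.null(mass)) NA_real_ else 1000 * vt / mass,
                 rr = breath$rr,
                 ptrans_peak = NA_real_, ptrans_endex = NA_real_,
                 dptrans = NA_real_, flags = flags),
            class = "breath_mechanics")
}

#' Add transpulmonary pressures to breath mechanics
#'
#' Transpulmonary pressure is `paw - peso`. Reports its cycle maximum, its
#' end-expiratory value (mean over the PEEP window; negative values are
#' physiological in lung injury) and the transpulmonary driving pressure,
#' defined as plateau transpulmonary pressure (mean over the plateau
#' window) minus the cycle minimum.
#'
#' @inheritParams breath_pressures
#' @param mech A `breath_mechanics` from [breath_pressures()].
#'
#' @return The updated `breath_mechanics`. When the recording has no
#'   esophageal channel the transpulmonary fields stay `NA` and a flag is
#'   added.
#' @export
transpulmonary <- function(rec, breath, mech, pause_window = 0.1,
                           peep_window = 0.1) {
  stopifnot(inherits(mech, "breath_mechanics"))
  if (is.null(rec$peso)) {
    mech$flags <- c(mech$flags, "no_peso")
    return(mech)
  }
  fs <- rec$sample_rate
  idx <- breath$onset:(breath$end - 1L)
  ptr <- rec$paw[idx] - rec$peso[idx]
  mech$ptrans_peak <- max(ptr)
  ew <- .win_idx(breath$insp_end, breath$end - 1L, fs, peep_window)
  mech$ptrans_endex <- mean(rec$paw[ew] - rec$peso[ew])
  if (!is.null(breath$pause)) {
    pw <- .win_idx(breath$pause[1L], breath$pause[2L], fs, pause_window)
    ptr_plat <- mean(rec$paw[pw] - rec$peso[pw])
    mech$dptrans <- ptr_plat - min(ptr)
  } else {
    mech$flags <- c(mech$flags, "no_pause_dptrans")
  }
  mech
}

#' Fit the equation of motion of the respiratory system
#'
#' Multiple linear regression of airway pressure on volume and flow over
#' the breath, excluding the end-inspiratory pause samples (zero-flow rows
#' are collinear with the intercept):
#' linear model `paw = E*V + R*V' + P0`; volume-dependent model
#' `paw = E1*V + E2*V^2 + R*V' + P0`, with the percentage of
#' volume-dependent elastance `%E2 = 100 * E2*VT / (E1 + E2*VT)` (signed;
#' negative values indicate recruitment-dominated, positive
#' overdistension-dominated mechanics).
#'
#' @inheritParams breath_pressures
#' @param model `"linear"` or `"volume_dependent"`.
#'
#' @return An object of class `eom_fit`: list with `model`, `E`, `R`,
#'   `E1`, `E2`, `P0`, `pct_e2`, `r_squared`, `n`.
#' @export
fit_equation_of_motion <- function(rec, breath,
                                   model = c("linear", "volume_dependent")) {
  model <- match.arg(model)
  stopifnot(inherits(rec, "waveform_recording"), inherits(breath, "breath"))
  idx <- breath$onset:(breath$end - 1L)
  vol <- integrate_volume(rec, breath)
  vt <- attr(vol, "vt")
  keep <- rep(TRUE, length(idx))
  if (!is.null(breath$pause))
    keep[(breath$pause[1L]:breath$pause[2L]) - breath$onset + 1L] <- FALSE
  V <- vol[keep]
  Vdot <- rec$flow[idx][keep]
  paw <- rec$paw[idx][keep]
  if (length(paw) < 20L)
    .stop_data("fit_equation_of_motion: need >= 20 samples, got %d", length(paw))
  df <- data.frame(paw = paw, V = V, Vdot = Vdot)
  fml <- if (model == "linear") paw ~ V + Vdot else paw ~ V + I(V^2) + Vdot
  fit <- stats::lm(fml, data = df)
  co <- stats::coef(fit)
  if (anyNA(co))
    .stop_data("fit_equation_of_motion: rank-deficient design (coefficients %s not estimable)",
               paste(names(co)[is.na(co)], collapse = ", "))
  ss_tot <- sum((paw - mean(paw))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  r2 <- min(max(r2, 0), 1)
  if (model == "linear") {
    out <- list(model = model, E = unname(co["V"]), R = unname(co["Vdot"]),
                E1 = unname(co["V"]), E2 = NA_real_,
                P0 = unname(co["(Intercept)"]), pct_e2 = NA_real_,
                r_squared = r2, n = length(paw), vt = vt)
  } else {
    e1 <- unname(co["V"]); e2 <- unname(co["I(V^2)"])
    out <- list(model = model, E = e1 + e2 * vt, R = unname(co["Vdot"]),
                E1 = e1, E2 = e2, P0 = unname(co["(Intercept)"]),
                pct_e2 = 100 * e2 * vt / (e1 + e2 * vt),
                r_squared = r2, n = length(paw), vt = vt)
  }
  structure(out, class = "eom_fit")
}
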