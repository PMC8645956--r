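# FDG kinetics: Patlak graphical analysis, irreversible two-tissue
# compartment fit, tissue-fraction normalization.

#' Arterial plasma input curve
#'
#' @param time_min Sample times in minutes from injection, strictly
#'   increasing, at least 3.
#' @param activity Plasma activity, kBq/ml, non-negative.
#'
#' @return Object of class `plasma_input` (a data frame).
#' @export
plasma_input <- function(time_min, activity) {
  if (length(time_min) < 3L)
    .stop_data("plasma_input: need >= 3 samples")
  if (any(diff(time_min) <= 0))
    .stop_data("plasma_input: times must be strictly increasing")
  if (any(activity < 0))
    .stop_data("plasma_input: activities must be >= 0")
  structure(data.frame(time_min = time_min, activity = activity),
            class = c("plasma_input", "data.frame"))
}

#' Region time-activity curve
#'
#' @param frame_start Frame start times, minutes.
#' @param duration Frame durations, minutes, positive; frames must be
#'   non-overlapping and increasing.
#' @param activity Frame mean activity, kBq/ml.
#' @param roi ROI label.
#'
#' @return Object of class `time_activity_curve` (a data frame with a
#'   `mid` column).
#' @export
time_activity_curve <- function(frame_start, duration, activity,
                                roi = "lung") {
  if (any(duration <= 0))
    .stop_data("time_activity_curve: durations must be > 0")
  ends <- frame_start + duration
  if (any(diff(frame_start) <= 0) ||
      any(frame_start[-1L] < ends[-length(ends)] - 1e-9))
    .stop_data("time_activity_curve: frames must be increasing and non-overlapping")
  structure(data.frame(frame_start = frame_start, duration = duration,
                       mid = frame_start + duration / 2,
                       activity = activity, roi = roi),
            class = c("time_activity_curve", "data.frame"))
}

#' Interpolate the plasma input and its running integral
#'
#' Piecewise-linear interpolation of the plasma activity; the running
#' integral from time 0 is the exact integral of that piecewise-linear
#' curve (trapezoid at the samples, quadratic continuation inside an
#' interval). Times before the first sample interpolate linearly from
#' (0, first activity).
#'
#' @param plasma A [plasma_input()].
#' @param t Times (min) within `[0, last sample]`.
#'
#' @return List with `activity` and `integral` at `t`.
#' @export
interpolate_plasma <- function(plasma, t) {
  stopifnot(inherits(plasma, "plasma_input"))
  pt <- plasma$time_min
  pa <- plasma$activity
  if (pt[1L] > 0) {
    pt <- c(0, pt)
    pa <- c(pa[1L], pa)
  }
  if (any(t < 0 - 1e-12) || any(t > pt[length(pt)] + 1e-9))
    .stop_data("interpolate_plasma: t outside [0, %.4g] min", pt[length(pt)])
  cp <- stats::approx(pt, pa, xout = t, rule = 1)$y
  cum <- .cumtrapz0(pt, pa)
  i <- findInterval(t, pt, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(pt) - 1L)
  int <- cum[i] + (t - pt[i]) * (pa[i] + cp) / 2
  list(activity = cp, integral = int)
}

#' Patlak graphical analysis
#'
#' Ordinary least squares of `y = C_T(t)/C_p(t)` on
#' `x = Int_0^t C_p / C_p(t)` over frames with mid-time at or after
#' `t_star`; the slope is the net uptake rate Ki (1/min), the intercept
#' the effective distribution volume.
#'
#' @param tac A [time_activity_curve()].
#' @param plasma A [plasma_input()].
#' @param t_star Linear-phase start time, minutes (default 20).
#' @param weights `"none"` (default) for unweighted OLS, or
#'   `"duration"` to weight frames by duration.
#'
#' @return Object of class `patlak_fit`: `ki`, `v0`, `t_star`,
#'   `r_squared`, `n`.
#' @export
patlak_fit <- function(tac, plasma, t_star = 20, weights = c("none", "duration")) {
  weights <- match.arg(weights)
  stopifnot(inherits(tac, "time_activity_curve"))
  sel <- tac$mid >= t_star
  mid <- tac$mid[sel]
  if (sum(sel) >= 1L) {
    ip <- interpolate_plasma(plasma, mid)
    ok <- ip$activity > 0
    mid <- mid[ok]
    y <- tac$activity[sel][ok] / ip$activity[ok]
    x <- ip$integral[ok] / ip$activity[ok]
    w <- if (weights == "duration") tac$duration[sel][ok] else NULL
  } else {
    x <- y <- numeric(0)
    w <- NULL
  }
  if (length(y) < 3L)
    .stop_data("patlak_fit: need >= 3 usable frames past t_star = %.3g, have %d",
               t_star, length(y))
  fit <- stats::lm(y ~ x, weights = w)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(ki = unname(stats::coef(fit)["x"]),
                 v0 = unname(stats::coef(fit)["(Intercept)"]),
                 t_star = t_star, r_squared = min(max(r2, 0), 1),
                 n = length(y)),
            class = "patlak_fit")
}

# Model frame means for the irreversible 2TC system on a fine grid.
# C_tissue(t) = K1*k3/(k2+k3) * Int Cp + K1*k2/(k2+k3) * exp(-(k2+k3)t) (*) Cp
# C_model = (1 - Vb) * C_tissue + Vb * C_blood, C_blood = plasma input.
.two_tc_frame_means <- function(theta, plasma, frame_start, duration,
                                dt = 0.05) {
  k1 <- theta[["K1"]]; k2 <- theta[["k2"]]; k3 <- theta[["k3"]]
  vb <- theta[["Vb"]]
  t_end <- max(frame_start + duration)
  tt <- seq(0, t_end, by = dt)
  ip <- interpolate_plasma(plasma, tt)
  cp <- ip$activity
  a <- k2 + k3
  if (a > 0) {
    # recursive trapezoid evaluation of the exponential convolution
    e <- exp(-a * dt)
    conv <- numeric(length(tt))
    for (i in 2:length(tt))
      conv[i] <- conv[i - 1L] * e + dt / 2 * (cp[i] + cp[i - 1L] * e)
    ct <- k1 * k3 / a * ip$integral + k1 * k2 / a * conv
  } else {
    ct <- k1 * ip$integral
  }
  cm <- (1 - vb) * ct + vb * cp
  cum <- .cumtrapz0(tt, cm)
  f0 <- stats::approx(tt, cum, xout = frame_start)$y
  f1 <- stats::approx(tt, cum, xout = frame_start + duration)$y
  (f1 - f0) / duration
}

#' Irreversible two-tissue-compartment fit
#'
#' Nonlinear least squares of the frame-averaged model
#' `C(t) = (1 - Vb) * C_2TC(t) + Vb * C_blood(t)` to a time-activity
#' curve, where `C_2TC` is the analytic solution of the irreversible
#' two-tissue compartment system and the blood curve is taken equal to
#' the plasma input (no hematocrit correction). Provides the blood
#' fraction `Vb` used in KiS normalization; the macro uptake rate
#' `K1*k3/(k2+k3)` is returned for cross-checking against the Patlak
#' slope.
#'
#' @param tac A [time_activity_curve()]; the first frame should start
#'   within the first minute so the vascular phase is seen.
#' @param plasma A [plasma_input()].
#' @param init Named starting values `K1`, `k2`, `k3`, `Vb`.
#' @param lower,upper Box constraints (rates >= 0, `Vb` in [0, 0.5]).
#' @param dt Fine-grid step (min) for the model evaluation.
#'
#' @return Object of class `compartment_fit`: `K1`, `k2`, `k3`, `Vb`,
#'   `ki` (macro rate), `residual_norm`, `vb_at_boundary` flag.
#' @export
fit_2tc_irreversible <- function(tac, plasma,
                                 init = c(K1 = 0.01, k2 = 0.1, k3 = 0.02,
                                          Vb = 0.05),
                                 lower = c(0, 0, 0, 0),
                                 upper = c(1, 5, 2, 0.5),
                                 dt = 0.05) {
  stopifnot(inherits(tac, "time_activity_curve"))
  if (tac$frame_start[1L] > 1)
    .stop_data("fit_2tc_irreversible: first frame starts at %.3g min; early vascular phase required (<= 1 min)",
               tac$frame_start[1L])
  obs <- tac$activity
  fstart <- tac$frame_start
  fdur <- tac$duration
  fit <- minpack.lm::nlsLM(
    obs ~ .two_tc_frame_means(c(K1 = K1, k2 = k2, k3 = k3, Vb = Vb),
                              plasma, fstart, fdur, dt),
    start = as.list(init), lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  conv <- fit$convInfo
  if (!is.null(conv$isConv) && !conv$isConv)
    .stop_data("fit_2tc_irreversible: did not converge (residual norm %.4g)",
               sqrt(sum(stats::residuals(fit)^2)))
  vb <- unname(co["Vb"])
  structure(list(K1 = unname(co["K1"]), k2 = unname(co["k2"]),
                 k3 = unname(co["k3"]), Vb = vb,
                 ki = unname(co["K1"] * co["k3"] / (co["k2"] + co["k3"])),
                 residual_norm = sqrt(sum(stats::residuals(fit)^2)),
                 vb_at_boundary = vb >= upper[4L] - 1e-6),
            class = "compartment_fit")
}

#' Tissue-fraction normalization of the FDG uptake rate
#'
#' `KiS = Ki / F_tissue = Ki / (1 - F_gas - F_blood)`: normalizing the
#' net uptake rate to the tissue fraction of the region removes the
#' dilution by gas and blood, so regions with equal tissue-level
#' metabolic activity but different aeration compare fairly.
#'
#' @param ki Net uptake rate, 1/min.
#' @param f_gas Gas fraction in [0, 1].
#' @param f_blood Blood fraction in [0, 1).
#' @param roi,timepoint Optional labels carried through.
#'
#' @return Object of class `kis_result`: `ki`, `f_gas`, `f_blood`,
#'   `f_tissue`, `kis`, `roi`, `timepoint`.
#' @export
normalize_kis <- function(ki, f_gas, f_blood, roi = NA_character_,
                          timepoint = NA_character_) {
  if (any(f_gas < 0 | f_gas > 1) || any(f_blood < 0 | f_blood >= 1))
    .stop_data("normalize_kis: fractions out of range")
  f_tissue <- 1 - f_gas - f_blood
  if (any(f_tissue <= 0))
    .stop_data("normalize_kis: F_gas + F_blood >= 1 leaves no tissue")
  structure(list(ki = ki, f_gas = f_gas, f_blood = f_blood,
                 f_tissue = f_tissue, kis = ki / f_tissue,
                 roi = roi, timepoint = timepoint),
            class = "kis_result")
}

#' ROI-median difference of KiS between two scans
#'
#' `delta_kis = median(second) - median(first)` over the voxel (or
#' animal) KiS values of the respective lung ROI.
#'
#' @param first,second Numeric vectors of KiS values (non-empty).
#'
#' @return Single numeric difference.
#' @export
delta_kis <- function(first, second) {
  if (!length(first) || !length(second))
    .stop_data("delta_kis: empty ROI")
  stats::median(second) - stats::median(first)
}
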