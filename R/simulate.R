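# Synthetic-data generators: every analysis input with known ground
# truth (ventilator waveforms, tracer curves, CT voxel fields, cohorts).

#' Ventilator settings for the waveform simulator
#'
#' Defaults reproduce the study conditions: volume-controlled
#' ventilation, tidal volume 6 ml/kg at the cohort's median body mass,
#' I:E 1:1, constant inspiratory flow 35 L/min, with the end-inspiratory
#' pause filling the remainder of the inspiratory time (pause duration =
#' inspiratory time - VT/flow).
#'
#' @param vt_ml_kg Tidal volume, ml/kg.
#' @param body_mass_kg Body mass, kg.
#' @param rr Respiratory rate, 1/min.
#' @param flow_l_min Inspiratory flow, L/min.
#' @param ie Inspiratory:expiratory time ratio (I/E).
#' @param sample_rate Sampling rate, Hz.
#'
#' @return Named list of settings.
#' @export
vent_settings <- function(vt_ml_kg = 6, body_mass_kg = 47.7, rr = 20,
                          flow_l_min = 35, ie = 1, sample_rate = 100) {
  stopifnot(vt_ml_kg > 0, body_mass_kg > 0, rr > 0, flow_l_min > 0,
            ie > 0, sample_rate > 0)
  list(vt_ml_kg = vt_ml_kg, body_mass_kg = body_mass_kg, rr = rr,
       flow_l_min = flow_l_min, ie = ie, sample_rate = sample_rate)
}

#' One-compartment lung model parameters
#'
#' @param e1 Volume-independent elastance, cmH2O/L (> 0).
#' @param e2 Volume-dependent elastance, cmH2O/L^2 (0 for a linear lung).
#' @param r Resistance, cmH2O.s/L (> 0).
#' @param e_cw Chest-wall elastance, cmH2O/L (drives esophageal pressure).
#' @param peep Set PEEP, cmH2O.
#' @param peso_baseline Esophageal pressure baseline, cmH2O.
#' @param noise_sd Gaussian noise SD added to both pressure channels,
#'   cmH2O (>= 0).
#'
#' @return Named list of parameters.
#' @export
lung_model <- function(e1 = 57.3, e2 = 0, r = 12.4, e_cw = 10, peep = 5,
                       peso_baseline = 3, noise_sd = 0) {
  stopifnot(e1 > 0, r > 0, noise_sd >= 0)
  list(e1 = e1, e2 = e2, r = r, e_cw = e_cw, peep = peep,
       peso_baseline = peso_baseline, noise_sd = noise_sd)
}

#' Simulate a volume-controlled ventilation recording
#'
#' Constant-flow inspiration, end-inspiratory pause, passive exponential
#' expiration with time constant `R/E1`. Airway pressure obeys the
#' equation of motion `paw = (E1 + E2*V)*V + R*V' + PEEP` evaluated on
#' the sampled flow and its discrete trapezoidal volume, so noiseless
#' recordings are fit exactly by [fit_equation_of_motion()]. The sampled
#' flow is shaped so its trapezoidal integral reaches the requested tidal
#' volume exactly at the start of the pause. Esophageal pressure is
#' `baseline + E_cw*V` plus noise. Deterministic given `seed`.
#'
#' @param settings From [vent_settings()].
#' @param lung From [lung_model()].
#' @param n_breaths Number of cycles.
#' @param seed Optional RNG seed (noise only).
#' @param meta Extra metadata merged into the recording's `meta`.
#'
#' @return A [waveform_recording()] with `vt_true` (L), `pause_s` and the
#'   generating parameters in `meta`.
#' @export
simulate_ventilation <- function(settings = vent_settings(),
                                 lung = lung_model(), n_breaths = 10,
                                 seed = NULL, meta = list()) {
  fs <- settings$sample_rate
  dt <- 1 / fs
  vt <- settings$vt_ml_kg * settings$body_mass_kg / 1000   # L
  flow <- settings$flow_l_min / 60                          # L/s
  t_cyc <- 60 / settings$rr
  t_insp <- t_cyc * settings$ie / (1 + settings$ie)
  m <- round(vt / flow * fs)                                # flow samples
  if (m < 2L)
    .stop_data("simulate_ventilation: flow phase shorter than 2 samples")
  n_insp <- round(t_insp * fs)
  if (m + 1L >= n_insp)
    .stop_data("simulate_ventilation: flow time %.3g s exceeds inspiratory time %.3g s",
               m * dt, t_insp)
  n_cyc <- round(t_cyc * fs)
  flow_eff <- vt / (m * dt)   # so the discrete integral hits vt exactly
  # passive expiration with time constant R/E1, capped so exhalation
  # completes within the expiratory window (no dynamic hyperinflation)
  tau <- min(lung$r / lung$e1, (t_cyc - t_insp) / 8)
  f <- numeric(n_cyc)
  f[seq_len(m)] <- flow_eff
  f[m + 1L] <- flow_eff / 2   # half-sample fall: trapezoid integral = vt
  exp_idx <- seq.int(n_insp + 1L, n_cyc)
  texp <- (exp_idx - 1L) * dt - t_insp
  f[exp_idx] <- -vt / tau * exp(-texp / tau)
  tcyc_s <- (seq_len(n_cyc) - 1L) * dt
  v <- .cumtrapz0(tcyc_s, f)
  # rescale expiratory flow so the discrete volume trace closes at zero
  # (the pause-to-expiration corner otherwise leaks half a sample of flow)
  s_exp <- v[n_cyc] - v[n_insp]
  if (s_exp < 0) f[exp_idx] <- f[exp_idx] * (vt / -s_exp)
  v <- .cumtrapz0(tcyc_s, f)
  paw <- lung$peep + (lung$e1 + lung$e2 * v) * v + lung$r * f
  peso <- lung$peso_baseline + lung$e_cw * v
  n <- n_cyc * n_breaths
  fvec <- rep(f, n_breaths)
  pawvec <- rep(paw, n_breaths)
  pesovec <- rep(peso, n_breaths)
  if (lung$noise_sd > 0) {
    noise <- .with_seed(seed, stats::rnorm(2L * n, sd = lung$noise_sd))
    pawvec <- pawvec + noise[seq_len(n)]
    pesovec <- pesovec + noise[seq.int(n + 1L, 2L * n)]
  }
  meta <- utils::modifyList(
    list(peep_set_cmh2o = lung$peep, rr_set = settings$rr,
         body_mass_kg = settings$body_mass_kg, vt_true = vt,
         pause_s = (n_insp - m) * dt, e1 = lung$e1, e2 = lung$e2,
         r = lung$r, e_cw = lung$e_cw), meta)
  waveform_recording(time = (seq_len(n) - 1L) * dt, paw = pawvec,
                     flow = fvec, peso = pesovec, sample_rate = fs,
                     meta = meta)
}

#' Feng-type arterial input function
#'
#' `Cp(t) = (A1*t - A2 - A3) * exp(l1*t) + A2*exp(l2*t) + A3*exp(l3*t)`,
#' a conventional FDG plasma input shape (activity in kBq/ml, time in
#' minutes).
#'
#' @param t Time, minutes.
#' @param a1,l1,a2,l2,a3,l3 Feng parameters (rates in 1/min).
#'
#' @return Plasma activity at `t`.
#' @export
feng_input <- function(t, a1 = 851.1, l1 = -4.13, a2 = 20.8, l2 = -0.12,
                       a3 = 21.9, l3 = -0.01) {
  (a1 * t - a2 - a3) * exp(l1 * t) + a2 * exp(l2 * t) + a3 * exp(l3 * t)
}

#' Tracer kinetics parameters for the PET simulator
#'
#' @param k1,k2,k3 Irreversible 2TC rate constants (K1 in ml/ml/min, k2
#'   and k3 in 1/min); the macro uptake rate is `K1*k3/(k2+k3)`.
#' @param vb Blood fraction in [0, 1). Default 0 (pure tissue curve);
#'   with `vb > 0` the Patlak slope on the mixed curve measures
#'   `(1 - vb) * Ki` — the vascular dilution that the tissue-fraction
#'   normalization ([normalize_kis()]) corrects.
#' @param frame_durations Frame durations (min) covering the dynamic
#'   scan; defaults span 75 min with short early frames.
#' @param plasma_times Plasma sampling times (min).
#' @param noise_scale Gaussian frame noise scale; frame SD =
#'   `noise_scale / sqrt(duration)`.
#'
#' @return Named list with a derived `ki_true`.
#' @export
tracer_params <- function(k1 = 0.01, k2 = 0.2, k3 = 0.05, vb = 0,
                          frame_durations = c(rep(0.25, 8), rep(0.5, 4),
                                              rep(1, 5), rep(2, 8),
                                              rep(5, 10)),
                          plasma_times = c(seq(0.25, 3, 0.25),
                                           seq(3.5, 10, 0.5),
                                           seq(11, 20, 1),
                                           seq(22.5, 75, 2.5)),
                          noise_scale = 0) {
  stopifnot(k1 >= 0, k2 >= 0, k3 >= 0, vb >= 0, vb < 1, noise_scale >= 0)
  list(k1 = k1, k2 = k2, k3 = k3, vb = vb,
       frame_durations = frame_durations, plasma_times = plasma_times,
       noise_scale = noise_scale,
       ki_true = if (k2 + k3 > 0) k1 * k3 / (k2 + k3) else 0)
}

#' Simulate a plasma input and tissue time-activity curve
#'
#' Plasma activity from the Feng model sampled at `plasma_times`; tissue
#' frame means from the analytic irreversible 2TC solution (with blood
#' fraction `vb`) averaged over the frame intervals; optional Gaussian
#' noise with SD scaled by `1/sqrt(duration)`. Deterministic given
#' `seed`.
#'
#' @param params From [tracer_params()].
#' @param seed Optional RNG seed (noise only).
#'
#' @return List with `plasma` ([plasma_input()]), `tac`
#'   ([time_activity_curve()]) and `ki_true` (1/min).
#' @export
simulate_tracer <- function(params = tracer_params(), seed = NULL) {
  plasma <- plasma_input(params$plasma_times,
                         pmax(feng_input(params$plasma_times), 0))
  starts <- cumsum(c(0, params$frame_durations))
  starts <- starts[-length(starts)]
  mu <- .two_tc_frame_means(c(K1 = params$k1, k2 = params$k2,
                              k3 = params$k3, Vb = params$vb),
                            plasma, starts, params$frame_durations)
  act <- mu
  if (params$noise_scale > 0) {
    eps <- .with_seed(seed, stats::rnorm(length(mu)))
    act <- mu + eps * params$noise_scale / sqrt(params$frame_durations)
  }
  list(plasma = plasma,
       tac = time_activity_curve(starts, params$frame_durations, act),
       ki_true = params$ki_true)
}

# Truncated-normal draw within [lo, hi] by inverse CDF.
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Simulate a CT voxel field with known aeration-compartment masses
#'
#' Voxel HU values are drawn from per-compartment Gaussians (means
#' -950/-700/-300/0 HU, SD 30) truncated to the compartment bins, so
#' class labels are exact by construction. Voxel counts per compartment
#' are chosen so the expected compartment *mass* fractions equal the
#' requested fractions (mass per voxel differs between compartments).
#' Deterministic given `seed`.
#'
#' @param fractions Length-4 numeric (hyper, normal, poor, non) mass
#'   fractions summing to 1.
#' @param n_voxels Total voxel count.
#' @param voxel_dims_mm Voxel edge lengths, mm.
#' @param seed Optional RNG seed.
#' @param means,sd Per-compartment HU means and common SD.
#'
#' @return List with `hu`, `labels` (factor), `mask` (all `TRUE`),
#'   `voxel_dims_mm` and the target `fractions`.
#' @export
simulate_ct <- function(fractions = c(hyper = 0.005, normal = 0.60,
                                      poor = 0.25, non = 0.145),
                        n_voxels = 1e5, voxel_dims_mm = c(1, 1, 1),
                        seed = NULL,
                        means = c(-950, -700, -300, 0), sd = 30) {
  fractions <- as.numeric(fractions)
  if (length(fractions) != 4L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    .stop_data("simulate_ct: fractions must be 4 non-negative values summing to 1")
  lo <- c(-1024, -900, -500, -100)
  hi <- c(-900, -500, -100, 100)
  # expected tissue fraction per compartment under the truncated normal
  a <- (lo - means) / sd; b <- (hi - means) / sd
  tmean <- means + sd * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
  tf <- 1 - pmin(pmax(tmean / -1000, 0), 1)
  w <- ifelse(fractions > 0, fractions / tf, 0)
  counts <- floor(n_voxels * w / sum(w))
  rem <- n_voxels - sum(counts)
  if (rem > 0) {
    frac <- n_voxels * w / sum(w) - counts
    counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1L
  }
  hu <- .with_seed(seed, {
    unlist(lapply(1:4, function(c)
      if (counts[c] > 0)
        .rtruncnorm(counts[c], means[c], sd, lo[c], hi[c]) else numeric(0)))
  })
  labels <- factor(rep(.AERATION_LEVELS, times = counts),
                   levels = .AERATION_LEVELS)
  list(hu = hu, labels = labels, mask = rep(TRUE, length(hu)),
       voxel_dims_mm = voxel_dims_mm, fractions = fractions)
}

#' Pearson correlation of a Gaussian copula targeting a Spearman rho
#'
#' Inverts the bivariate-normal relation
#' `rho_S = (6/pi) * asin(rho_P / 2)`.
#'
#' @param rho_s Target (population) Spearman correlation.
#'
#' @return The Pearson correlation to use in the copula.
#' @export
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

#' Expected sample Spearman rho under a bivariate normal copula
#'
#' Moran's finite-sample expectation
#' `E[r_S] = 6 / (pi * (n + 1)) * (asin(rho) + (n - 2) * asin(rho / 2))`
#' for Pearson correlation `rho`; the small-n estimate is biased toward
#' zero relative to the population value.
#'
#' @param rho_pearson Copula Pearson correlation.
#' @param n Sample size.
#'
#' @return Expected sample Spearman correlation.
#' @export
expected_spearman <- function(rho_pearson, n) {
  6 / (pi * (n + 1)) * (asin(rho_pearson) + (n - 2) * asin(rho_pearson / 2))
}

#' Cohort specification for the multi-animal simulator
#'
#' Defaults emulate the study: eight animals, two imaging timepoints,
#' a target rank correlation of 0.74 between median mechanical power and
#' the KiS change, KiS medians 0.0136 (first) and 0.0320 (second) 1/min,
#' MP median 13.5 (IQR 4.9) J/min, and an all-positive KiS-difference
#' configuration.
#'
#' @param n Animals (>= 3).
#' @param rho Target Spearman correlation between MP and delta KiS.
#' @param mp_median,mp_iqr Median and IQR of per-animal median MP, J/min.
#' @param kis_first_median,kis_first_iqr First-scan KiS marginal, 1/min.
#' @param dkis_median Median KiS increase, 1/min.
#' @param dkis_sdlog Log-normal spread of the KiS increase.
#' @param all_positive Force every animal's second KiS above its first
#'   (log-normal increase), as observed in the study.
#'
#' @return Named list.
#' @export
cohort_spec <- function(n = 8, rho = 0.74, mp_median = 13.5, mp_iqr = 4.9,
                        kis_first_median = 0.0136, kis_first_iqr = 0.0041,
                        dkis_median = 0.0184, dkis_sdlog = 0.5,
                        all_positive = TRUE) {
  stopifnot(n >= 3, rho >= -1, rho <= 1)
  list(n = n, rho = rho, mp_median = mp_median, mp_iqr = mp_iqr,
       kis_first_median = kis_first_median, kis_first_iqr = kis_first_iqr,
       dkis_median = dkis_median, dkis_sdlog = dkis_sdlog,
       all_positive = all_positive)
}

#' Simulate a multi-animal, two-timepoint cohort
#'
#' A Gaussian copula links per-animal median mechanical power and the
#' KiS change with the target rank correlation ([spearman_to_pearson()]);
#' marginals are scaled to the specified medians/IQRs (normal for MP,
#' log-normal for the KiS increase so all differences are positive when
#' requested). MP components are proportional splits (elastic 2/3,
#' resistive 1/3), so their ranks equal the MP ranks. Other respiratory
#' medians, the aeration pair and the blood-gas panel are drawn
#' independently of the KiS change. Per-animal lung parameters
#' (`e_true`, `r_true`, `rr_set`) are solved so that a waveform
#' simulated from them yields the animal's target MP under the
#' PEEP-referenced energy convention. Deterministic given `seed`.
#'
#' @param spec From [cohort_spec()].
#' @param seed RNG seed.
#'
#' @return List with data frames `animals` (per-animal medians, KiS pair
#'   and lung parameters), `aeration` (per animal/timepoint masses and
#'   volumes), `bloodgas` (per animal/timepoint panel) and the effective
#'   `spec`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  .with_seed(seed, {
    n <- spec$n
    rp <- spearman_to_pearson(spec$rho)
    z1 <- stats::rnorm(n)
    z2 <- rp * z1 + sqrt(1 - rp^2) * stats::rnorm(n)
    sd_from_iqr <- function(iqr) iqr / (2 * stats::qnorm(0.75))
    mp <- spec$mp_median + sd_from_iqr(spec$mp_iqr) * z1
    mp <- pmax(mp, 7)   # keep above the resistive floor of the lung model
    if (spec$all_positive) {
      dkis <- stats::qlnorm(stats::pnorm(z2), log(spec$dkis_median),
                            spec$dkis_sdlog)
    } else {
      dkis <- spec$dkis_median + sd_from_iqr(spec$dkis_median) * z2
    }
    kis1 <- pmax(spec$kis_first_median +
                   sd_from_iqr(spec$kis_first_iqr) * stats::rnorm(n), 1e-4)
    # lung parameters reproducing mp under the peep-referenced convention
    settings <- vent_settings()
    vt <- settings$vt_ml_kg * settings$body_mass_kg / 1000
    fl <- settings$flow_l_min / 60
    r_true <- pmax(stats::rnorm(n, 12.4, 1.5), 6)
    rr_set <- pmax(round(stats::rnorm(n, 31, 3)), 12)
    me_target <- mp / rr_set / .CMH2O_L_TO_J          # cmH2O.L
    e_true <- pmax(2 * (me_target - r_true * fl * vt) / vt^2, 10)
    animals <- data.frame(
      animal = sprintf("pig%02d", seq_len(n)),
      mp = mp, mp_elastic = 2 / 3 * mp, mp_resistive = 1 / 3 * mp,
      kis_first = kis1, kis_second = kis1 + dkis, delta_kis = dkis,
      ppeak = stats::rnorm(n, 28.9, 2), pplat = stats::rnorm(n, 24.5, 1.5),
      dp = stats::rnorm(n, 19.1, 2), dptrans = stats::rnorm(n, 21.6, 2.5),
      rr = rr_set, elastance = e_true, resistance = r_true,
      pct_e2 = stats::rnorm(n, -24.6, 3),
      e_true = e_true, r_true = r_true, rr_set = rr_set)
    aeration <- data.frame(
      animal = rep(animals$animal, each = 2L),
      timepoint = rep(c("first", "second"), n),
      total_mass_g = as.vector(rbind(stats::rnorm(n, 854.1, 90),
                                     stats::rnorm(n, 635.6, 70))),
      gas_volume_ml = as.vector(rbind(stats::rnorm(n, 850.7, 80),
                                      stats::rnorm(n, 780.2, 90))),
      hyper_pct = as.vector(rbind(stats::rlnorm(n, log(0.48), 0.5),
                                  stats::rlnorm(n, log(0.75), 0.5))))
    bloodgas <- data.frame(
      animal = rep(animals$animal, each = 2L),
      timepoint = rep(c("0h", "18h"), n),
      pao2 = pmax(stats::rnorm(2 * n, 107, 15), 60),
      paco2 = as.vector(rbind(stats::rnorm(n, 46.4, 6),
                              stats::rnorm(n, 60.2, 4))),
      pha = stats::rnorm(2 * n, 7.41, 0.03),
      fio2 = pmin(pmax(stats::rnorm(2 * n, 0.32, 0.03), 0.25), 1),
      hb = stats::rnorm(2 * n, 9.5, 1),
      sao2 = pmin(stats::rnorm(2 * n, 0.96, 0.02), 1),
      svo2 = pmin(stats::rnorm(2 * n, 0.70, 0.05), 0.95),
      pvo2 = stats::rnorm(2 * n, 40, 4),
      co = pmax(as.vector(rbind(stats::rnorm(n, 6.2, 1),
                                stats::rnorm(n, 7.1, 1))), 2),
      hr = pmax(as.vector(rbind(stats::rnorm(n, 120, 15),
                                stats::rnorm(n, 104, 15))), 60))
    list(animals = animals, aeration = aeration, bloodgas = bloodgas,
         spec = spec)
  })
}
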