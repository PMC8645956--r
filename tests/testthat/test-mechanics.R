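test_that("breath pressures match the one-compartment closed form", {
  # E = 60, VT = 0.3, PEEP 5 -> Pplat = 23, dP = E*VT = 18
  rec <- ref_recording()
  b <- segment_breaths(rec)[[2]]
  m <- breath_pressures(rec, b)
  expect_equal(m$pplat, 23.0, tolerance = 1e-6)
  expect_equal(m$peep, 5.0, tolerance = 0.005)
  expect_equal(m$dp, 18.0, tolerance = 0.005)
  expect_equal(m$vt, 0.3, tolerance = 1e-9)
  expect_equal(m$vt_ml_kg, 6, tolerance = 1e-9)
  expect_gte(m$ppeak, m$pplat)
  expect_length(m$flags, 0)

  # with 0.2 cmH2O white noise dP stays within 0.2 of 18
  recn <- ref_recording(noise_sd = 0.2, seed = 4)
  bn <- segment_breaths(recn)[[2]]
  expect_lt(abs(breath_pressures(recn, bn)$dp - 18), 0.2)
})

test_that("constant airway pressure collapses all pressure summaries", {
  t <- seq(0, 2.99, by = 0.01)
  fl <- rep(c(rep(0.3, 50), rep(0, 25), rep(-0.3, 75)), 2)
  rec <- waveform_recording(t, rep(5, length(t)), fl)
  b <- segment_breaths(rec, min_duration = 0.5)[[1]]
  m <- breath_pressures(rec, b)
  expect_equal(m$ppeak, 5)
  expect_equal(m$pmean, 5)
  expect_equal(m$peep, 5)
  expect_equal(m$dp, 0)
})

test_that("breaths without a pause flag plateau as unavailable", {
  t <- seq(0, 2.99, by = 0.01)
  fl <- rep(c(rep(0.3, 75), rep(-0.3, 75)), 2)   # no zero-flow pause
  rec <- waveform_recording(t, 5 + cumsum(fl) * 0.1, fl)
  b <- segment_breaths(rec)[[1]]
  m <- breath_pressures(rec, b)
  expect_true(is.na(m$pplat))
  expect_true(is.na(m$dp))
  expect_true("no_pause" %in% m$flags)
})

test_that("transpulmonary pressures follow the paw - peso convention", {
  rec <- ref_recording()
  b <- segment_breaths(rec)[[2]]
  m <- transpulmonary(rec, b, breath_pressures(rec, b))
  # plateau Ptrans = Pplat - (baseline + E_cw*VT) = 23 - 6 = 17; the cycle
  # minimum sits at expiration onset where the elastic terms still equal
  # the plateau's, minus the resistive dip R*VT/tau (tau = 0.1875 s here)
  expect_equal(m$dptrans, 12 * 0.3 / 0.1875, tolerance = 0.02)

  # peso identically zero -> Ptrans peak equals Ppeak
  rec0 <- rec
  rec0$peso <- rep(0, length(rec$peso))
  m0 <- transpulmonary(rec0, b, breath_pressures(rec0, b))
  expect_equal(m0$ptrans_peak, breath_pressures(rec0, b)$ppeak)

  # end-expiratory Ptrans may be negative (peso baseline above PEEP)
  rec_neg <- simulate_ventilation(
    vent_settings(rr = 20, body_mass_kg = 50),
    lung_model(e1 = 60, r = 12, peep = 5, peso_baseline = 8),
    n_breaths = 3)
  bn <- segment_breaths(rec_neg)[[2]]
  mn <- transpulmonary(rec_neg, bn, breath_pressures(rec_neg, bn))
  expect_equal(mn$ptrans_endex, -3, tolerance = 0.02)

  # no esophageal channel: fields unavailable, flagged
  rec_np <- rec
  rec_np$peso <- NULL
  mnp <- transpulmonary(rec_np, b, breath_pressures(rec_np, b))
  expect_true(is.na(mnp$ptrans_peak))
  expect_true("no_peso" %in% mnp$flags)
})

test_that("equation-of-motion fit is exact on noiseless model data", {
  rec <- simulate_ventilation(
    vent_settings(rr = 20, body_mass_kg = 47.7),
    lung_model(e1 = 57.3, r = 12.4, peep = 5), n_breaths = 3)
  b <- segment_breaths(rec)[[2]]
  f <- fit_equation_of_motion(rec, b, "linear")
  expect_equal(f$E, 57.3, tolerance = 1e-7)
  expect_equal(f$R, 12.4, tolerance = 1e-7)
  expect_equal(f$P0, 5, tolerance = 1e-7)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
})

test_that("volume-dependent fit recovers E1, E2 and a signed %E2", {
  rec <- simulate_ventilation(
    vent_settings(rr = 20, body_mass_kg = 47.7),
    lung_model(e1 = 70, e2 = -40, r = 12.4, peep = 5), n_breaths = 3)
  b <- segment_breaths(rec)[[2]]
  f <- fit_equation_of_motion(rec, b, "volume_dependent")
  expect_equal(f$E1, 70, tolerance = 1e-6)
  expect_equal(f$E2, -40, tolerance = 1e-6)
  vt <- f$vt
  expect_equal(f$pct_e2, 100 * (-40) * vt / (70 - 40 * vt), tolerance = 1e-6)
  expect_lt(f$pct_e2, 0)

  # linear model on the same data reports E without E2
  fl <- fit_equation_of_motion(rec, b, "linear")
  expect_true(is.na(fl$E2))
  expect_true(is.na(fl$pct_e2))
})

test_that("zero flow gives a rank-deficient design error", {
  t <- seq(0, 2.99, by = 0.01)
  rec <- waveform_recording(t, rep(5, length(t)), rep(0, length(t)))
  b <- structure(list(onset = 1L, insp_end = 150L, end = 300L,
                      pause = NULL, duration = 3, rr = 20),
                 class = "breath")
  expect_error(fit_equation_of_motion(rec, b), "rank-deficient")
})

test_that("E and R recover within 5 % under 0.5 cmH2O noise", {
  errs <- t(vapply(1:100, function(s) {
    rec <- ref_recording(n_breaths = 2, noise_sd = 0.5, seed = s)
    b <- segment_breaths(rec)[[1]]
    f <- fit_equation_of_motion(rec, b, "linear")
    c(abs(f$E - 60) / 60, abs(f$R - 12) / 12)
  }, numeric(2)))
  expect_lt(max(errs[, 1]), 0.05)
  expect_lt(max(errs[, 2]), 0.05)
})
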