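test_that("numerical mechanical energy matches the constant-flow closed form", {
  rec <- ref_recording()
  b <- segment_breaths(rec)[[2]]
  m <- breath_pressures(rec, b)
  flow <- 35 / 60

  me_atm <- mechanical_energy(rec, b, "atmospheric")
  expect_equal(me_atm, closed_form_me(60, 12, 0.3, flow, peep = 5),
               tolerance = 0.005)

  me_peep <- mechanical_energy(rec, b, "peep", peep = m$peep)
  expect_equal(me_peep, closed_form_me(60, 12, 0.3, flow),
               tolerance = 0.005)

  # atmospheric exceeds peep-referenced by exactly PEEP_measured * VT
  expect_equal(me_atm - me_peep, m$peep * m$vt * cmh2o_l_to_joule(),
               tolerance = 1e-12)

  # zero driving pressure: paw constant at the reference -> ME = 0
  t <- seq(0, 2.99, by = 0.01)
  fl <- rep(c(rep(0.3, 50), rep(0, 25), rep(-0.3, 75)), 2)
  rec0 <- waveform_recording(t, rep(0, length(t)), fl)
  b0 <- segment_breaths(rec0)[[1]]
  expect_equal(mechanical_energy(rec0, b0, "atmospheric"), 0)
})

test_that("mechanical power is energy times rate", {
  expect_equal(mechanical_power(0.4707, 20), 9.414)
  expect_equal(mechanical_power(0, 37), 0)
  expect_equal(mechanical_power(0.5, 10), mechanical_power(0.5, 20) / 2)
  expect_error(mechanical_power(0.5, 0), "positive")
  expect_error(mechanical_power(0.5, -5), "positive")
})

test_that("elastic/resistive decomposition is residual-closed", {
  rec <- ref_recording(noise_sd = 0.3, seed = 21)
  b <- segment_breaths(rec)[[2]]
  f <- fit_equation_of_motion(rec, b, "linear")
  pw <- decompose_power(rec, b, f, "peep")
  flow <- 35 / 60
  expect_equal(pw$me_resistive, 12 * flow * 0.3 * cmh2o_l_to_joule(),
               tolerance = 0.01)
  expect_lt(abs(pw$me_total - pw$me_elastic - pw$me_resistive), 1e-9)
  expect_lt(abs(pw$mp_total - pw$mp_elastic - pw$mp_resistive), 1e-6)

  # zero-resistance lung: all energy is elastic
  rec0 <- simulate_ventilation(vent_settings(rr = 20, body_mass_kg = 50),
                               lung_model(e1 = 60, r = 1e-6, peep = 5),
                               n_breaths = 3)
  b0 <- segment_breaths(rec0)[[2]]
  f0 <- fit_equation_of_motion(rec0, b0, "linear")
  pw0 <- decompose_power(rec0, b0, f0, "peep")
  expect_equal(pw0$me_resistive, 0, tolerance = 1e-6)
  expect_equal(pw0$me_elastic, pw0$me_total, tolerance = 1e-6)

  # missing fit: total still reported, components unavailable
  pwna <- decompose_power(rec, b, NULL, "peep")
  expect_false(is.na(pwna$me_total))
  expect_true(is.na(pwna$me_elastic))
})

test_that("median power summaries follow the sorted-midpoint convention", {
  df <- data.frame(mp_total = c(3, 1, 2), mp_elastic = c(2, 0.5, 1),
                   mp_resistive = c(1, 0.5, 1))
  expect_equal(summarize_power(df)[["mp_total"]], 2)
  df4 <- data.frame(mp_total = c(4, 1, 2, 3))
  expect_equal(summarize_power(df4)[["mp_total"]], 2.5)
  expect_equal(summarize_power(df4, window = 2:3)[["mp_total"]], 1.5)
  expect_error(summarize_power(df4[0, , drop = FALSE]), "no breaths")
  # identical breaths: median equals the single-breath value
  expect_equal(summarize_power(data.frame(mp_total = rep(7.7, 5)))[["mp_total"]],
               7.7)
})

test_that("power scales linearly in RR and quadratically in VT for pure elastance", {
  mp_at <- function(vt_ml_kg, rr) {
    rec <- simulate_ventilation(
      vent_settings(rr = rr, body_mass_kg = 50, vt_ml_kg = vt_ml_kg),
      lung_model(e1 = 60, r = 1e-6, peep = 5), n_breaths = 3)
    b <- segment_breaths(rec)[[2]]
    pw <- decompose_power(rec, b, reference = "peep",
                          peep = breath_pressures(rec, b)$peep)
    pw$mp_total
  }
  base <- mp_at(4, 15)
  expect_equal(mp_at(4, 30) / base, 2, tolerance = 0.01)
  expect_equal(mp_at(8, 15) / base, 4, tolerance = 0.01)
})

test_that("a declining-power schedule is recovered monotone from waveforms", {
  out <- run_pipeline(run_config(scenario = "table1_like", seed = 5,
                                 output_dir = withr::local_tempdir()))
  med <- out$timepoint_medians
  expect_equal(med$timepoint, c("0h", "6h", "12h", "18h"))
  expect_true(all(diff(med$mp) < 0))
})

test_that("full analysis on noisy waveforms recovers E, R and MP", {
  rec <- ref_recording(n_breaths = 5, noise_sd = 0.3, seed = 33)
  pb <- analyze_recording(rec, model = "linear", reference = "atmospheric")
  expect_equal(nrow(pb), 5)
  expect_equal(median(pb$e), 60, tolerance = 0.05)
  expect_equal(median(pb$r), 12, tolerance = 0.05)
  closed <- closed_form_me(60, 12, 0.3, 35 / 60, peep = 5) * 20
  expect_equal(median(pb$mp_total), closed, tolerance = 0.02)
  expect_lt(max(abs(pb$mp_total - pb$mp_elastic - pb$mp_resistive)), 1e-6)
})
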