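# Shared fixtures built in code.

# Noiseless reference recording: linear lung E = 60, R = 12, PEEP 5,
# VT 0.3 L (6 ml/kg x 50 kg), RR 20, flow 35 L/min, 100 Hz.
ref_recording <- function(n_breaths = 3, noise_sd = 0, e2 = 0, seed = NULL) {
  simulate_ventilation(
    vent_settings(rr = 20, body_mass_kg = 50, vt_ml_kg = 6),
    lung_model(e1 = 60, e2 = e2, r = 12, peep = 5, noise_sd = noise_sd),
    n_breaths = n_breaths, seed = seed)
}

# Closed-form inspiratory PV-loop energy (J) for a constant-flow breath.
closed_form_me <- function(e, r, vt, flow, peep = 0) {
  (peep * vt + e * vt^2 / 2 + r * flow * vt) * cmh2o_l_to_joule()
}

# Rank permutation of 1..8 with sum of squared rank differences 22
# (rho = 1 - 132/504 = 0.738).
perm_sd2_22 <- c(3, 4, 1, 2, 7, 5, 6, 8)
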