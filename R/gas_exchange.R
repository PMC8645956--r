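# Derived gas-exchange and hemodynamic indices.

#' Default physiological constants for gas-exchange formulas
#'
#' @param patm Barometric pressure, mmHg.
#' @param ph2o Water vapour pressure at body temperature, mmHg.
#' @param rq Respiratory quotient.
#' @param hb_o2_capacity O2 binding capacity of hemoglobin, ml O2 per g Hb.
#' @param o2_solubility Dissolved O2, ml/dl per mmHg.
#'
#' @return Named list of constants.
#' @export
gas_constants <- function(patm = 760, ph2o = 47, rq = 0.8,
                          hb_o2_capacity = 1.34, o2_solubility = 0.0031) {
  list(patm = patm, ph2o = ph2o, rq = rq,
       hb_o2_capacity = hb_o2_capacity, o2_solubility = o2_solubility)
}

#' PaO2/FiO2 (Horovitz) ratio
#'
#' @param pao2 Arterial O2 partial pressure, mmHg.
#' @param fio2 Inspired O2 fraction, > 0.
#'
#' @return Ratio in mmHg.
#' @export
pf_ratio <- function(pao2, fio2) {
  if (any(fio2 <= 0)) .stop_data("pf_ratio: fio2 must be > 0")
  pao2 / fio2
}

#' Alveolar O2 partial pressure (alveolar gas equation)
#'
#' `PAO2 = FiO2 * (Patm - PH2O) - PaCO2 / RQ`.
#'
#' @param fio2 Inspired O2 fraction.
#' @param paco2 Arterial CO2 partial pressure, mmHg.
#' @param constants From [gas_constants()].
#'
#' @return Alveolar PO2, mmHg.
#' @export
alveolar_po2 <- function(fio2, paco2, constants = gas_constants()) {
  fio2 * (constants$patm - constants$ph2o) - paco2 / constants$rq
}

#' Alveolo-arterial oxygen difference
#'
#' `AaDO2 = PAO2 - PaO2` with PAO2 from the alveolar gas equation.
#'
#' @param pao2 Arterial O2 partial pressure, mmHg.
#' @inheritParams alveolar_po2
#'
#' @return AaDO2, mmHg.
#' @export
aado2 <- function(pao2, paco2, fio2, constants = gas_constants()) {
  alveolar_po2(fio2, paco2, constants) - pao2
}

#' Blood O2 content
#'
#' `CxO2 = 1.34 * Hb * SxO2 + 0.0031 * PxO2` (ml O2 / dl).
#'
#' @param hb Hemoglobin, g/dl.
#' @param so2 O2 saturation, fraction in [0, 1].
#' @param po2 O2 partial pressure, mmHg.
#' @param constants From [gas_constants()].
#'
#' @return O2 content, ml/dl.
#' @export
o2_content <- function(hb, so2, po2, constants = gas_constants()) {
  constants$hb_o2_capacity * hb * so2 + constants$o2_solubility * po2
}

#' Venous admixture (shunt fraction)
#'
#' `Qs/Qt = (CcO2 - CaO2) / (CcO2 - CvO2)` with end-capillary blood
#' assumed fully saturated at alveolar PO2.
#'
#' @param hb Hemoglobin, g/dl.
#' @param sao2,pao2 Arterial saturation (fraction) and PO2 (mmHg).
#' @param svo2,pvo2 Mixed-venous saturation (fraction) and PO2 (mmHg).
#' @param pao2_alv Alveolar PO2 (mmHg), e.g. from [alveolar_po2()].
#' @param constants From [gas_constants()].
#'
#' @return Shunt fraction.
#' @export
venous_admixture <- function(hb, sao2, pao2, svo2, pvo2, pao2_alv,
                             constants = gas_constants()) {
  cc <- o2_content(hb, 1.0, pao2_alv, constants)
  ca <- o2_content(hb, sao2, pao2, constants)
  cv <- o2_content(hb, svo2, pvo2, constants)
  if (any(cc <= cv))
    .stop_data("venous_admixture: capillary content <= venous content")
  (cc - ca) / (cc - cv)
}

#' Stroke volume from cardiac output and heart rate
#'
#' `SV = 1000 * CO / HR` (ml).
#'
#' @param co Cardiac output, L/min.
#' @param hr Heart rate, 1/min, > 0.
#'
#' @return Stroke volume, ml.
#' @export
stroke_volume <- function(co, hr) {
  if (any(hr <= 0)) .stop_data("stroke_volume: hr must be > 0")
  1000 * co / hr
}

#' Derived indices for a blood-gas/hemodynamic panel
#'
#' @param panel Data frame with columns `pao2`, `paco2`, `fio2`, `hb`,
#'   `sao2`, `svo2`, `pvo2` and optionally `co`, `hr` (one row per
#'   animal/timepoint; extra columns are carried through).
#' @param constants From [gas_constants()].
#'
#' @return The panel with added columns `pf`, `aado2`,
#'   `venous_admixture` and (when `co`/`hr` exist) `sv`.
#' @export
derive_indices <- function(panel, constants = gas_constants()) {
  need <- c("pao2", "paco2", "fio2", "hb", "sao2", "svo2", "pvo2")
  miss <- setdiff(need, names(panel))
  if (length(miss))
    .stop_data("derive_indices: missing columns: %s", paste(miss, collapse = ", "))
  pao2_alv <- alveolar_po2(panel$fio2, panel$paco2, constants)
  panel$pf <- pf_ratio(panel$pao2, panel$fio2)
  panel$aado2 <- pao2_alv - panel$pao2
  panel$venous_admixture <- venous_admixture(panel$hb, panel$sao2, panel$pao2,
                                             panel$svo2, panel$pvo2,
                                             pao2_alv, constants)
  if (all(c("co", "hr") %in% names(panel)))
    panel$sv <- stroke_volume(panel$co, panel$hr)
  panel
}
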