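# Quantitative CT: gas fraction, aeration compartments, lung mass.

.AERATION_LEVELS <- c("hyper", "normal", "poor", "non")

#' CT gas fraction
#'
#' `F_gas = HU / -1000`, clipped to [0, 1]: -1000 HU is pure gas, 0 HU
#' water-equivalent tissue; positive HU clips to zero gas.
#'
#' @param hu Hounsfield units (finite).
#'
#' @return Gas fraction(s) in [0, 1].
#' @export
gas_fraction <- function(hu) {
  if (any(!is.finite(hu))) .stop_data("gas_fraction: non-finite HU")
  pmin(pmax(hu / -1000, 0), 1)
}

#' Classify voxels into aeration compartments
#'
#' Hyper-aerated below -900 HU, normally aerated [-900, -500), poorly
#' aerated [-500, -100), non-aerated at or above -100 HU. Bins are
#' left-closed on the denser side.
#'
#' @param hu Hounsfield units (finite).
#'
#' @return Factor with levels `hyper`, `normal`, `poor`, `non`.
#' @export
classify_aeration <- function(hu) {
  if (any(!is.finite(hu))) .stop_data("classify_aeration: non-finite HU")
  cut(hu, breaks = c(-Inf, -900, -500, -100, Inf),
      labels = .AERATION_LEVELS, right = FALSE)
}

#' Summarize lung aeration from masked CT voxels
#'
#' Per masked voxel the tissue fraction is `1 - F_gas`; voxel mass is
#' voxel volume (ml) times tissue fraction times 1.0 g/ml
#' (water-equivalent density); gas volume is voxel volume times `F_gas`.
#' Masses are accumulated per aeration compartment; relative masses are
#' percentages of total lung mass. The net aerated relative mass is the
#' sum of the hyper, normal and poor compartments. Voxels outside
#' [-1024, 100] HU are counted but flagged in `qc` (artifact guard).
#'
#' @param hu Numeric vector or array of HU values (a full CT volume).
#' @param mask Optional logical/0-1 vector or array selecting lung
#'   voxels; `NULL` uses all voxels. Must select at least one voxel.
#' @param voxel_dims_mm Voxel edge lengths in mm (length 3).
#'
#' @return Object of class `aeration_summary`: `total_mass_g`,
#'   `gas_volume_ml`, `lung_volume_ml`, `mass_g` and `relative_mass_pct`
#'   (named by compartment), `net_aerated_pct`, `n_voxels`, `qc`.
#' @export
summarize_aeration <- function(hu, mask = NULL, voxel_dims_mm = c(1, 1, 1)) {
  if (any(voxel_dims_mm <= 0))
    .stop_data("summarize_aeration: voxel dims must be > 0")
  hu <- as.numeric(hu)
  if (!is.null(mask)) {
    mask <- as.logical(mask)
    if (length(mask) != length(hu))
      .stop_data("summarize_aeration: mask/volume size mismatch")
    hu <- hu[mask]
  }
  if (!length(hu)) .stop_data("summarize_aeration: empty mask")
  vox_ml <- prod(voxel_dims_mm) / 1000
  fgas <- gas_fraction(hu)
  cls <- classify_aeration(hu)
  mass_vox <- vox_ml * (1 - fgas)          # 1.0 g/ml tissue density
  mass <- vapply(split(mass_vox, cls), sum, numeric(1))
  total <- sum(mass_vox)
  rel <- if (total > 0) 100 * mass / total else rep(NA_real_, 4)
  names(rel) <- names(mass) <- .AERATION_LEVELS
  structure(list(
    total_mass_g = total,
    gas_volume_ml = sum(fgas) * vox_ml,
    lung_volume_ml = length(hu) * vox_ml,
    mass_g = mass,
    relative_mass_pct = rel,
    net_aerated_pct = sum(rel[c("hyper", "normal", "poor")]),
    n_voxels = length(hu),
    qc = list(n_outside_hu_range = sum(hu < -1024 | hu > 100))),
    class = "aeration_summary")
}

#' Read a CT volume and lung mask from NIfTI files
#'
#' @param ct_path Path to the CT NIfTI file (HU values).
#' @param mask_path Optional path to a binary lung-mask NIfTI file.
#'
#' @return List with `hu` (array), `mask` (logical array or `NULL`) and
#'   `voxel_dims_mm`.
#' @export
read_ct_nifti <- function(ct_path, mask_path = NULL) {
  img <- RNifti::readNifti(ct_path)
  dims <- RNifti::pixdim(img)[1:3]
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- RNifti::readNifti(mask_path)
    if (!all(dim(m) == dim(img)))
      .stop_data("read_ct_nifti: mask and CT dimensions differ")
    mask <- as.array(m) > 0
  }
  list(hu = as.array(img), mask = mask, voxel_dims_mm = dims)
}

#' Summarize aeration from a voxel-count HU histogram
#'
#' Mask-free desk-testing entry: a table of HU values with voxel counts.
#'
#' @param hu HU bin values.
#' @param count Voxel counts per bin (non-negative integers).
#' @param voxel_dims_mm Voxel edge lengths in mm.
#'
#' @return An `aeration_summary` (see [summarize_aeration()]).
#' @export
summarize_aeration_hist <- function(hu, count, voxel_dims_mm = c(1, 1, 1)) {
  if (length(hu) != length(count) || any(count < 0))
    .stop_data("summarize_aeration_hist: invalid histogram")
  summarize_aeration(rep(hu, times = count), voxel_dims_mm = voxel_dims_mm)
}

#' Differences between two aeration summaries
#'
#' Second minus first, field by field (including per-compartment masses
#' and relative masses).
#'
#' @param first,second `aeration_summary` objects.
#'
#' @return Named list of differences.
#' @export
delta_aeration <- function(first, second) {
  stopifnot(inherits(first, "aeration_summary"),
            inherits(second, "aeration_summary"))
  list(total_mass_g = second$total_mass_g - first$total_mass_g,
       gas_volume_ml = second$gas_volume_ml - first$gas_volume_ml,
       lung_volume_ml = second$lung_volume_ml - first$lung_volume_ml,
       mass_g = second$mass_g - first$mass_g,
       relative_mass_pct = second$relative_mass_pct - first$relative_mass_pct,
       net_aerated_pct = second$net_aerated_pct - first$net_aerated_pct)
}
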