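# Physical constants used throughout the marker engine.
# 1 mmHg = 133.322 Pa exactly (conventional value); hence
# 1 mmHg * 1 mL = 133.322 Pa * 1e-6 m^3 = 1.33322e-4 J.
MMHG_TO_PA <- 133.322
MMHG_ML_TO_J <- 1.33322e-4
MYOCARDIAL_DENSITY_G_PER_ML <- 1.05

#' Canonical marker names
#'
#' The 23 left-ventricular markers computed by [compute_panel()], in the
#' canonical order used by every ranking table and output file.
#'
#' @return Character vector of length 23.
#' @export
marker_names <- function() {
  c("glased", "glase", "glase_bsa", "glase_ht27",
    "pressure_strain_product", "gls_abs", "lame_stress",
    "stroke_work", "sw_bsa", "sw_ht27", "sw_lvmass",
    "lvgfi", "lvef", "lvcf",
    "lv_mass", "lvm_bsa", "lvm_ht27",
    "edv", "edv_bsa", "edv_ht27",
    "edd", "edd_bsa", "edd_ht27")
}

#' Marker orientation registry
#'
#' Declared adverse direction for each marker, used to sign-orient per-SD
#' hazard ratios so that HR >= 1 always corresponds to the adverse direction
#' (lower contractile function or larger chamber/mass).  The registry is
#' data, not logic: energy, strain, stress, stroke-work and
#' ejection/contraction/global-function markers are adverse when LOW;
#' mass, volume and diameter markers are adverse when HIGH.
#'
#' @return data.frame with columns `marker`, `adverse` ("low"/"high") and
#'   `sign` (-1 when low is adverse: the oriented covariate is the negated
#'   z-score, so a positive coefficient means low values raise hazard).
#' @export
marker_orientation <- function() {
  low_adverse <- c("glased", "glase", "glase_bsa", "glase_ht27",
                   "pressure_strain_product", "gls_abs", "lame_stress",
                   "stroke_work", "sw_bsa", "sw_ht27", "sw_lvmass",
                   "lvgfi", "lvef", "lvcf")
  m <- marker_names()
  data.frame(marker = m,
             adverse = ifelse(m %in% low_adverse, "low", "high"),
             sign = ifelse(m %in% low_adverse, -1, 1),
             stringsAsFactors = FALSE)
}
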