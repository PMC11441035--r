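# Marker engine: left-ventricular structural and contractile-function
# markers from CMR-derived base measurements.
#
# Base measurements (one row per subject):
#   edv, esv              end-diastolic / end-systolic volume [mL]
#   lvmv                  LV muscle (myocardial) volume [mL]
#   inner_diameter_ed     mean end-diastolic endocardial diameter [mm]
#   wall_thickness_ed     mean end-diastolic wall thickness [mm]
#   gls_percent           peak global longitudinal strain [%], negative
#                         for physiological shortening
#   sbp_mmhg              brachial systolic blood pressure [mmHg]
# plus anthropometrics height_m [m] and weight_kg [kg].

.check_positive <- function(x, name, strict = TRUE) {
  bad <- if (strict) !is.na(x) & x <= 0 else !is.na(x) & x < 0
  if (any(bad))
    stop(sprintf("'%s' must be %s (offending value: %g)",
                 name, if (strict) "positive" else "non-negative",
                 x[which(bad)[1L]]), call. = FALSE)
  invisible(x)
}

#' Body surface area
#'
#' Du Bois & Du Bois formula (default): BSA = 0.007184 * weight^0.425 *
#' height_cm^0.725, with height in centimetres.  Mosteller
#' (sqrt(height_cm * weight / 3600)) is available as an alternative.
#'
#' @param height_m height in metres.
#' @param weight_kg weight in kilograms.
#' @param formula `"dubois"` (default) or `"mosteller"`.
#' @return body surface area in m^2.
#' @examples
#' compute_bsa(1.80, 80) # 1.996
#' @export
compute_bsa <- function(height_m, weight_kg,
                        formula = c("dubois", "mosteller")) {
  formula <- match.arg(formula)
  .check_positive(height_m, "height_m")
  .check_positive(weight_kg, "weight_kg")
  h_cm <- 100 * height_m
  switch(formula,
         dubois = 0.007184 * weight_kg^0.425 * h_cm^0.725,
         mosteller = sqrt(h_cm * weight_kg / 3600))
}

#' LV mass from myocardial volume
#'
#' Myocardial tissue density 1.05 g/mL.
#'
#' @param lvmv_ml LV muscle volume in mL.
#' @return mass in grams.
#' @export
compute_lv_mass <- function(lvmv_ml) {
  .check_positive(lvmv_ml, "lvmv_ml")
  MYOCARDIAL_DENSITY_G_PER_ML * lvmv_ml
}

#' LV global function index
#'
#' LVGFI = SV / (LVMV + (ESV + EDV)/2), as a percentage.
#'
#' @param edv,esv,lvmv volumes in mL, with `edv > esv > 0` and `lvmv > 0`.
#'   `edv == esv` (zero stroke volume) is admitted as a boundary case.
#' @return percent.
#' @export
compute_lvgfi <- function(edv, esv, lvmv) {
  .check_positive(esv, "esv")
  .check_positive(lvmv, "lvmv")
  .check_positive(edv - esv, "edv - esv", strict = FALSE)
  100 * (edv - esv) / (lvmv + (esv + edv) / 2)
}

#' LV contraction fraction
#'
#' LVCF = SV / LVMV (dimensionless ratio).
#'
#' @inheritParams compute_lvgfi
#' @export
compute_lvcf <- function(edv, esv, lvmv) {
  .check_positive(esv, "esv")
  .check_positive(lvmv, "lvmv")
  .check_positive(edv - esv, "edv - esv", strict = FALSE)
  (edv - esv) / lvmv
}

#' Stroke work
#'
#' Estimated as stroke volume times systolic blood pressure, converted to
#' joules: 1 mmHg * mL = 1.33322e-4 J.
#'
#' @param edv,esv volumes in mL.
#' @param sbp_mmhg systolic blood pressure in mmHg.
#' @return energy in J.
#' @export
compute_stroke_work <- function(edv, esv, sbp_mmhg) {
  .check_positive(esv, "esv")
  .check_positive(sbp_mmhg, "sbp_mmhg")
  .check_positive(edv - esv, "edv - esv", strict = FALSE)
  (edv - esv) * sbp_mmhg * MMHG_ML_TO_J
}

#' Pressure-strain product
#'
#' |GLS| (%) times systolic blood pressure (mmHg).
#'
#' @param gls_percent peak global longitudinal strain in percent (signed).
#' @param sbp_mmhg systolic blood pressure in mmHg.
#' @return product in %*mmHg.
#' @export
compute_pressure_strain_product <- function(gls_percent, sbp_mmhg) {
  .check_positive(sbp_mmhg, "sbp_mmhg")
  abs(gls_percent) * sbp_mmhg
}

#' Lame thick-wall longitudinal stress
#'
#' Peak nominal longitudinal stress of a thick-walled cylinder evaluated on
#' the pre-deformed (end-diastolic) geometry:
#' sigma_l = P_i * r_i^2 / (r_o^2 - r_i^2), where P_i is the cuff systolic
#' pressure converted to Pa, r_i half the mean end-diastolic endocardial
#' diameter, and r_o = r_i + mean end-diastolic wall thickness.
#'
#' @param sbp_mmhg systolic blood pressure in mmHg.
#' @param inner_diameter_ed mean end-diastolic endocardial diameter in mm.
#' @param wall_thickness_ed mean end-diastolic wall thickness in mm.
#' @return stress in kPa.
#' @examples
#' compute_lame_stress(120, 50, 10) # 16.665 kPa
#' @export
compute_lame_stress <- function(sbp_mmhg, inner_diameter_ed,
                                wall_thickness_ed) {
  .check_positive(sbp_mmhg, "sbp_mmhg", strict = FALSE)
  .check_positive(inner_diameter_ed, "inner_diameter_ed")
  .check_positive(wall_thickness_ed, "wall_thickness_ed")
  r_i <- inner_diameter_ed / 2
  r_o <- r_i + wall_thickness_ed
  p_i <- sbp_mmhg * MMHG_TO_PA
  # radii in mm: the mm^2 factors cancel in the ratio
  (p_i * r_i^2 / (r_o^2 - r_i^2)) / 1000
}

#' Global longitudinal active strain energy density
#'
#' GLASED = 1/2 * |sigma_l| * |eps_l|, the longitudinal mechanical work per
#' unit myocardial volume; stress in kPa times dimensionless strain gives
#' kJ/m^3.
#'
#' @param lame_stress_kpa longitudinal wall stress in kPa (>= 0).
#' @param gls_percent peak GLS in percent (signed; magnitude used).
#' @return energy density in kJ/m^3.
#' @export
compute_glased <- function(lame_stress_kpa, gls_percent) {
  .check_positive(lame_stress_kpa, "lame_stress_kpa", strict = FALSE)
  0.5 * lame_stress_kpa * abs(gls_percent) / 100
}

#' Global longitudinal active strain energy
#'
#' GLASE = GLASED * LVMV: kJ/m^3 times mL (= 1e-6 m^3) gives millijoules,
#' returned in joules.
#'
#' @param glased_kj_m3 GLASED in kJ/m^3 (>= 0).
#' @param lvmv_ml LV muscle volume in mL (>= 0).
#' @return energy in J.
#' @export
compute_glase <- function(glased_kj_m3, lvmv_ml) {
  .check_positive(glased_kj_m3, "glased_kj_m3", strict = FALSE)
  .check_positive(lvmv_ml, "lvmv_ml", strict = FALSE)
  glased_kj_m3 * lvmv_ml * 1e-3
}

#' Index a marker to a body-size basis
#'
#' Divides a marker by body surface area, height^2.7 or LV mass.
#'
#' @param value marker value.
#' @param basis positive scalar or vector: bsa (m^2), height_m^2.7, or LV
#'   mass (g).
#' @return indexed value.
#' @export
index_marker <- function(value, basis) {
  .check_positive(basis, "index basis")
  value / basis
}

#' Compute the 23-marker LV panel
#'
#' Takes one row per subject of base CMR measurements plus anthropometrics
#' and returns the full marker panel in canonical order.  `bsa_m2` is
#' derived from height and weight unless supplied.  Rows with missing base
#' fields get `NA` for the markers that need them and are flagged
#' incomplete; non-missing values violating the physiological domain
#' (e.g. `esv >= edv`, non-positive volumes) raise an error naming the
#' offending field.
#'
#' @param records data.frame with columns `edv`, `esv`, `lvmv`,
#'   `inner_diameter_ed`, `wall_thickness_ed`, `gls_percent`, `sbp_mmhg`,
#'   `height_m`, `weight_kg` (and optionally `bsa_m2`).
#' @param bsa_formula `"dubois"` or `"mosteller"`.
#' @return data.frame with the 23 marker columns of [marker_names()] plus a
#'   logical `complete` column.
#' @examples
#' rec <- data.frame(edv = 135, esv = 60, lvmv = 100, inner_diameter_ed = 50,
#'                   wall_thickness_ed = 10, gls_percent = -18,
#'                   sbp_mmhg = 120, height_m = 1.75, weight_kg = 80)
#' compute_panel(rec)$glased # 1.5 kJ/m^3
#' @export
compute_panel <- function(records, bsa_formula = c("dubois", "mosteller")) {
  bsa_formula <- match.arg(bsa_formula)
  records <- as.data.frame(records)
  need <- c("edv", "esv", "lvmv", "inner_diameter_ed", "wall_thickness_ed",
            "gls_percent", "sbp_mmhg", "height_m", "weight_kg")
  for (f in setdiff(need, names(records))) records[[f]] <- NA_real_

  with_marker <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("marker '%s': %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  bsa <- if (!is.null(records$bsa_m2)) records$bsa_m2 else
    with_marker("bsa", compute_bsa(records$height_m, records$weight_kg,
                                   bsa_formula))
  ht27 <- records$height_m^2.7

  out <- data.frame(row.names = seq_len(nrow(records)))
  out$lame_stress <- with_marker("lame_stress",
    compute_lame_stress(records$sbp_mmhg, records$inner_diameter_ed,
                        records$wall_thickness_ed))
  out$glased <- with_marker("glased",
    compute_glased(out$lame_stress, records$gls_percent))
  out$glase <- with_marker("glase",
    compute_glase(out$glased, records$lvmv))
  out$glase_bsa <- with_marker("glase_bsa", index_marker(out$glase, bsa))
  out$glase_ht27 <- with_marker("glase_ht27", index_marker(out$glase, ht27))
  out$pressure_strain_product <- with_marker("pressure_strain_product",
    compute_pressure_strain_product(records$gls_percent, records$sbp_mmhg))
  out$gls_abs <- abs(records$gls_percent)
  out$stroke_work <- with_marker("stroke_work",
    compute_stroke_work(records$edv, records$esv, records$sbp_mmhg))
  out$sw_bsa <- with_marker("sw_bsa", index_marker(out$stroke_work, bsa))
  out$sw_ht27 <- with_marker("sw_ht27", index_marker(out$stroke_work, ht27))
  out$lv_mass <- with_marker("lv_mass", compute_lv_mass(records$lvmv))
  out$sw_lvmass <- with_marker("sw_lvmass",
    index_marker(out$stroke_work, out$lv_mass))
  out$lvgfi <- with_marker("lvgfi",
    compute_lvgfi(records$edv, records$esv, records$lvmv))
  out$lvef <- with_marker("lvef", {
    .check_positive(records$edv, "edv")
    100 * (records$edv - records$esv) / records$edv
  })
  out$lvcf <- with_marker("lvcf",
    compute_lvcf(records$edv, records$esv, records$lvmv))
  out$lvm_bsa <- with_marker("lvm_bsa", index_marker(out$lv_mass, bsa))
  out$lvm_ht27 <- with_marker("lvm_ht27", index_marker(out$lv_mass, ht27))
  out$edv <- records$edv
  out$edv_bsa <- with_marker("edv_bsa", index_marker(records$edv, bsa))
  out$edv_ht27 <- with_marker("edv_ht27", index_marker(records$edv, ht27))
  out$edd <- records$inner_diameter_ed
  out$edd_bsa <- with_marker("edd_bsa",
    index_marker(records$inner_diameter_ed, bsa))
  out$edd_ht27 <- with_marker("edd_ht27",
    index_marker(records$inner_diameter_ed, ht27))

  out <- out[, marker_names()]
  out$complete <- stats::complete.cases(out)
  rownames(out) <- NULL
  out
}

#' Read base measurements from CSV and write the marker panel
#'
#' @param infile CSV with the columns documented in [compute_panel()].
#' @param outfile destination CSV for the 23-marker panel.
#' @param bsa_formula `"dubois"` or `"mosteller"`.
#' @return the panel, invisibly.
#' @export
markers_csv <- function(infile, outfile,
                        bsa_formula = c("dubois", "mosteller")) {
  rec <- data.table::fread(infile, data.table = FALSE)
  panel <- compute_panel(rec, bsa_formula = match.arg(bsa_formula))
  data.table::fwrite(panel, outfile)
  invisible(panel)
}
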