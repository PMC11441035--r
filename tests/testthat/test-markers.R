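# marker engine: formula correctness against hand arithmetic and an
# independent spreadsheet-style recomputation, domain errors, invariants.

test_that("single-marker formulas match hand arithmetic", {
  # BSA (Du Bois); printed to 3 decimals
  expect_equal(compute_bsa(1.80, 80), 1.996, tolerance = 5e-4)
  expect_equal(compute_bsa(1.60, 60), 1.622, tolerance = 5e-4)
  expect_equal(compute_bsa(1.80, 80, "mosteller"),
               sqrt(180 * 80 / 3600), tolerance = 1e-12)

  expect_equal(compute_lv_mass(100), 105)
  expect_equal(compute_lv_mass(87.3), 91.665)

  expect_equal(compute_lvgfi(135, 60, 100), 100 * 75 / 197.5,
               tolerance = 1e-12)
  expect_equal(compute_lvgfi(140, 56, 120), 100 * 84 / 218,
               tolerance = 1e-12)
  expect_equal(compute_lvgfi(60, 60, 100), 0)

  expect_equal(compute_lvcf(135, 60, 100), 0.75)
  expect_equal(compute_lvcf(144, 64, 64), 1.25)

  expect_equal(compute_stroke_work(135, 60, 120), 9000 * 1.33322e-4,
               tolerance = 1e-12)
  expect_equal(compute_stroke_work(135, 60, 120),
               compute_stroke_work(120, 60, 150))  # equal-product check
  expect_equal(compute_stroke_work(60, 60, 120), 0)

  expect_equal(compute_pressure_strain_product(-18, 120), 2160)
  expect_equal(compute_pressure_strain_product(-9, 240), 2160)
  expect_equal(compute_pressure_strain_product(0, 120), 0)
})

test_that("Lame stress and the energy markers match hand arithmetic", {
  # sbp 120 -> P_i = 15998.64 Pa; r_i 25, r_o 35: 625/600
  expect_equal(compute_lame_stress(120, 50, 10),
               120 * 133.322 * 625 / 600 / 1000, tolerance = 1e-12)
  expect_equal(compute_lame_stress(120, 50, 10), 16.665, tolerance = 1e-4)
  expect_equal(compute_lame_stress(0, 50, 10), 0)
  # thicker wall lowers stress: r_o 45 -> 625/1400
  expect_equal(compute_lame_stress(120, 50, 20),
               120 * 133.322 * 625 / 1400 / 1000, tolerance = 1e-12)
  expect_lt(compute_lame_stress(120, 50, 20),
            compute_lame_stress(120, 50, 10))

  expect_equal(compute_glased(16.66525, -18), 0.5 * 16.66525 * 0.18,
               tolerance = 1e-12)
  expect_equal(compute_glased(20, -15), 1.5)
  expect_equal(compute_glased(16, 0), 0)

  expect_equal(compute_glase(1.5, 100), 0.15)
  expect_equal(compute_glase(2.0, 150), 0.30)
  expect_equal(compute_glase(0, 100), 0)
})

test_that("domain violations are rejected with the field named", {
  expect_error(compute_bsa(1.0, 0), "weight_kg")
  expect_error(compute_lv_mass(0), "lvmv")
  expect_error(compute_lvgfi(60, 75, 100), "edv - esv")
  expect_error(compute_lame_stress(120, 50, 0), "wall_thickness_ed")
  expect_error(index_marker(10, 0), "basis")
  expect_error(compute_panel(within(worked_record(), esv <- 200)), "edv")
})

test_that("index_marker divides by the basis and inverts exactly", {
  expect_equal(index_marker(105, 2.0), 52.5)
  expect_equal(index_marker(42.17, 1), 42.17)
  expect_equal(index_marker(1.2, 105), 1.2 / 105, tolerance = 1e-15)
  set.seed(3)
  v <- runif(50, 0.1, 500); b <- runif(50, 0.5, 3)
  expect_equal(index_marker(v, b) * b, v, tolerance = 1e-12)
})

test_that("compute_panel produces the worked record and exactly 23 markers", {
  panel <- compute_panel(worked_record())
  expect_identical(setdiff(names(panel), "complete"), marker_names())
  expect_length(marker_names(), 23)
  expect_true(panel$complete)
  expect_equal(panel$glased, 1.500, tolerance = 1e-4)
  expect_equal(panel$lvef, 100 * 75 / 135, tolerance = 1e-12)
  expect_equal(panel$lvcf, 0.75)
  expect_equal(panel$stroke_work, 1.200, tolerance = 1e-4)
  expect_equal(panel$glase, panel$glased * 100 * 1e-3, tolerance = 1e-12)
  expect_equal(panel$glase_bsa * 2.0, panel$glase, tolerance = 1e-12)
})

test_that("zero strain zeroes the energy markers but not the volumetric ones", {
  rec <- within(worked_record(), gls_percent <- 0)
  panel <- compute_panel(rec)
  expect_equal(panel$glased, 0)
  expect_equal(panel$glase, 0)
  expect_equal(panel$pressure_strain_product, 0)
  expect_equal(panel$gls_abs, 0)
  expect_equal(panel$lvef, 100 * 75 / 135, tolerance = 1e-12)
  expect_equal(panel$lv_mass, 105)
})

test_that("missing fields give NA markers, others computed, flagged incomplete", {
  rec <- worked_record()
  rec$gls_percent <- NA_real_
  panel <- compute_panel(rec)
  expect_true(is.na(panel$glased))
  expect_true(is.na(panel$pressure_strain_product))
  expect_equal(panel$lvef, 100 * 75 / 135, tolerance = 1e-12)
  expect_false(panel$complete)
})

test_that("panel agrees with the spreadsheet-style oracle on 100 random records", {
  rec <- random_records(100, seed = 42)
  panel <- compute_panel(rec)
  oracle <- t(apply(rec, 1, function(row)
    oracle_panel_row(as.list(row))))
  for (m in marker_names())
    expect_equal(panel[[m]], unname(oracle[, m]), tolerance = 1e-10,
                 label = m)
})

test_that("panel invariants hold on random records", {
  rec <- random_records(200, seed = 7)
  panel <- compute_panel(rec)
  bsa <- compute_bsa(rec$height_m, rec$weight_kg)
  ht27 <- rec$height_m^2.7
  expect_true(all(panel$glased >= 0))
  # conservation: glase / lvmv reproduces glased
  expect_equal(panel$glase * 1e3 / rec$lvmv, panel$glased,
               tolerance = 1e-12)
  # indexed x basis = unindexed, relative error < 1e-12
  expect_equal(panel$glase_bsa * bsa, panel$glase, tolerance = 1e-12)
  expect_equal(panel$glase_ht27 * ht27, panel$glase, tolerance = 1e-12)
  expect_equal(panel$sw_bsa * bsa, panel$stroke_work, tolerance = 1e-12)
  expect_equal(panel$sw_lvmass * panel$lv_mass, panel$stroke_work,
               tolerance = 1e-12)
  expect_equal(panel$lvm_ht27 * ht27, panel$lv_mass, tolerance = 1e-12)
  expect_equal(panel$edd_bsa * bsa, panel$edd, tolerance = 1e-12)
  expect_equal(panel$edv_ht27 * ht27, panel$edv, tolerance = 1e-12)
})

test_that("stress is monotone in pressure and diameter, anti-monotone in wall", {
  sbp <- seq(90, 200, by = 10)
  expect_true(all(diff(compute_lame_stress(sbp, 50, 10)) > 0))
  di <- seq(35, 65, by = 2.5)
  expect_true(all(diff(compute_lame_stress(120, di, 10)) > 0))
  wt <- seq(4, 16, by = 1)
  expect_true(all(diff(compute_lame_stress(120, 50, wt)) < 0))
  # homogeneity degree 1 in pressure
  expect_equal(compute_lame_stress(240, 50, 10),
               2 * compute_lame_stress(120, 50, 10), tolerance = 1e-12)
  expect_equal(compute_pressure_strain_product(-18, 240),
               2 * compute_pressure_strain_product(-18, 120))
  expect_equal(compute_stroke_work(135, 60, 240),
               2 * compute_stroke_work(135, 60, 120), tolerance = 1e-12)
})

test_that("markers CSV round trip preserves the panel", {
  rec <- random_records(20, seed = 5)
  fin <- tempfile(fileext = ".csv"); fout <- tempfile(fileext = ".csv")
  data.table::fwrite(rec, fin)
  panel <- markers_csv(fin, fout)
  back <- data.table::fread(fout, data.table = FALSE)
  expect_identical(names(back), c(marker_names(), "complete"))
  expect_equal(back$glased, panel$glased, tolerance = 1e-9)
  unlink(c(fin, fout))
})
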