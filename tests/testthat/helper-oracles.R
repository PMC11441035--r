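# Independent oracles used across the suite.  Everything here is written
# against definitions, not against the package's own code paths.

# Naive Efron partial log-likelihood for a single covariate, by direct
# risk-set enumeration (O(n^2)); used with optimize() as a grid-style
# maximizer independent of the Newton-Raphson engine.
oracle_efron_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    wD <- sum(exp(beta * x[D]))
    wR <- sum(exp(beta * x[R]))
    ll <- ll + beta * sum(x[D]) -
      sum(log(wR - ((seq_len(d) - 1) / d) * wD))
  }
  ll
}

oracle_cox_beta <- function(x, time, event, interval = c(-8, 8)) {
  stats::optimize(oracle_efron_loglik, interval, x = x, time = time,
                  event = event, maximum = TRUE, tol = 1e-10)$maximum
}

# O(n^2) pair-enumeration concordance with the same conventions as the
# implementation contract: event-anchored, tied times unusable, tied
# scores 1/2.
oracle_concordance <- function(risk, time, event) {
  num <- den <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (event[i] != 1 || time[j] <= time[i]) next
    den <- den + 1
    if (risk[i] > risk[j]) num <- num + 1
    else if (risk[i] == risk[j]) num <- num + 0.5
  }
  if (den == 0) NA_real_ else num / den
}

# Spreadsheet-style recomputation of the full panel for one record,
# written as flat arithmetic.
oracle_panel_row <- function(r) {
  sv <- r$edv - r$esv
  bsa <- 0.007184 * r$weight_kg^0.425 * (100 * r$height_m)^0.725
  ht27 <- r$height_m^2.7
  ri <- r$inner_diameter_ed / 2
  ro <- ri + r$wall_thickness_ed
  stress_kpa <- r$sbp_mmhg * 133.322 * ri^2 / (ro^2 - ri^2) / 1000
  glased <- 0.5 * stress_kpa * abs(r$gls_percent) / 100
  glase <- glased * r$lvmv / 1000
  sw <- sv * r$sbp_mmhg * 1.33322e-4
  mass <- 1.05 * r$lvmv
  c(glased = glased, glase = glase, glase_bsa = glase / bsa,
    glase_ht27 = glase / ht27,
    pressure_strain_product = abs(r$gls_percent) * r$sbp_mmhg,
    gls_abs = abs(r$gls_percent), lame_stress = stress_kpa,
    stroke_work = sw, sw_bsa = sw / bsa, sw_ht27 = sw / ht27,
    sw_lvmass = sw / mass,
    lvgfi = 100 * sv / (r$lvmv + (r$esv + r$edv) / 2),
    lvef = 100 * sv / r$edv, lvcf = sv / r$lvmv,
    lv_mass = mass, lvm_bsa = mass / bsa, lvm_ht27 = mass / ht27,
    edv = r$edv, edv_bsa = r$edv / bsa, edv_ht27 = r$edv / ht27,
    edd = r$inner_diameter_ed, edd_bsa = r$inner_diameter_ed / bsa,
    edd_ht27 = r$inner_diameter_ed / ht27)
}

# random valid base-measurement records
random_records <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    edv = runif(n, 90, 220), esv = runif(n, 30, 85),
    lvmv = runif(n, 50, 140),
    inner_diameter_ed = runif(n, 38, 62),
    wall_thickness_ed = runif(n, 4, 12),
    gls_percent = runif(n, -25, -8),
    sbp_mmhg = runif(n, 95, 185),
    height_m = runif(n, 1.5, 1.95), weight_kg = runif(n, 50, 110))
}

# small survival datasets for oracle comparisons
random_survival <- function(n, seed, beta = 0.5, tie_round = NULL) {
  set.seed(seed)
  x <- rnorm(n)
  t <- rexp(n, exp(beta * x))
  cc <- runif(n, 0, 2)
  time <- pmin(t, cc)
  if (!is.null(tie_round)) time <- round(time, tie_round) + 0.01
  list(x = x, time = time, event = as.integer(t <= cc))
}

worked_record <- function() {
  data.frame(edv = 135, esv = 60, lvmv = 100, inner_diameter_ed = 50,
             wall_thickness_ed = 10, gls_percent = -18, sbp_mmhg = 120,
             height_m = 1.75, weight_kg = 80, bsa_m2 = 2.0)
}

small_test_cohort <- function(n = 4000, seed = 11) {
  sample_cohort(default_generator_config(n), seed = seed)
}
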