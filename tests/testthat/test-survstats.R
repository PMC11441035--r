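# Kaplan-Meier, log-rank, concordance, Schoenfeld and Holm: hand-worked
# examples, O(n^2) oracles, and cross-checks against the survival package.

test_that("KM equals hand product-limit and 1 - ECDF without censoring", {
  # times {1, 2+, 3}, events at 1 and 3: S = 2/3 after 1, 0 after 3
  fit <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(fit$time, c(1, 3))
  expect_equal(fit$survival, c(2 / 3, 0), tolerance = 1e-12)
  # no censoring: 1 - ECDF at the event times
  set.seed(4)
  t5 <- sort(runif(5))
  f5 <- km_estimate(t5, rep(1, 5))
  expect_equal(f5$survival, 1 - seq_len(5) / 5, tolerance = 1e-12)
  # time-scale equivariance
  f2 <- km_estimate(2 * t5, rep(1, 5))
  expect_equal(f2$time, 2 * f5$time)
  expect_equal(f2$survival, f5$survival)
  # all-censored input: S identically 1 with a warning
  expect_warning(f0 <- km_estimate(c(1, 2), c(0, 0)), "no events")
  expect_identical(nrow(f0), 0L)
  expect_equal(km_survival_at(f5, 0), 1)
})

test_that("KM and both cumulative-hazard estimators match survival::survfit", {
  skip_if_not_installed("survival")
  d <- random_survival(300, seed = 9, tie_round = 1)
  fit <- km_estimate(d$time, d$event)
  sf <- survival::survfit(survival::Surv(d$time, d$event) ~ 1)
  ss <- summary(sf, times = fit$time)
  expect_equal(fit$survival, ss$surv, tolerance = 1e-12)
  expect_equal(fit$n_risk, ss$n.risk)
  expect_equal(fit$cumhaz, -log(fit$survival), tolerance = 1e-12)
  na <- km_estimate(d$time, d$event, cumhaz = "nelson_aalen")
  expect_equal(na$cumhaz, cumsum(na$n_event / na$n_risk), tolerance = 1e-12)
})

test_that("tertile_split cuts at empirical thirds with deterministic ties", {
  g <- tertile_split(1:9)
  expect_equal(as.integer(g), rep(1:3, each = 3))
  # ties at the cut go to the lower tertile, deterministically
  v <- c(rep(1, 5), rep(2, 5), rep(3, 5))
  g1 <- tertile_split(v); g2 <- tertile_split(v)
  expect_identical(as.integer(g1), as.integer(g2))
  expect_true(all(g1[v == 1] == 1))
  expect_error(tertile_split(c(1, 1, 2)), "3 distinct")
  # near-balanced sizes on continuous data
  set.seed(8)
  big <- rnorm(44957)
  expect_lte(diff(range(tabulate(tertile_split(big), 3))), 2)
})

test_that("log-rank matches a hand-computed 2-group table and survdiff", {
  # groups A: times 1, 3 (events); B: times 2, 4 (censored) -- worked by
  # hand: at t=1 N=4, n_A=2, d=1: E_A = 1/2, V = (2*2*1*3)/(16*3) = 1/4
  #        at t=3 N=2, n_A=1, d=1: E_A = 1/2, V = (1*1*1*1)/(4*1) = 1/4
  # O_A - E_A = 2 - 1 = 1; V = 1/2; chi2 = 2
  lr <- log_rank_test(c(1, 3, 2, 4), c(1, 1, 0, 0), c("A", "A", "B", "B"))
  expect_equal(lr$statistic, 2, tolerance = 1e-12)
  expect_equal(unname(lr$observed), c(2, 0))
  expect_equal(unname(lr$expected), c(1, 1), tolerance = 1e-12)
  # identical copies of one group -> statistic 0, p = 1
  d0 <- random_survival(40, seed = 12)
  lr0 <- log_rank_test(rep(d0$time, 2), rep(d0$event, 2),
                       rep(1:2, each = 40))
  expect_equal(lr0$statistic, 0, tolerance = 1e-9)
  expect_equal(lr0$p, 1, tolerance = 1e-9)
  expect_error(log_rank_test(d0$time, d0$event, rep(1, 40)), "2 groups")

  skip_if_not_installed("survival")
  for (s in 1:3) {
    d <- random_survival(200, seed = 30 + s, tie_round = 1)
    g <- sample(1:3, 200, replace = TRUE)
    lr3 <- log_rank_test(d$time, d$event, g)
    ref <- survival::survdiff(survival::Surv(d$time, d$event) ~ g)
    expect_equal(lr3$statistic, ref$chisq, tolerance = 1e-9)
    expect_equal(unname(lr3$expected), unname(ref$exp), tolerance = 1e-9)
  }
})

test_that("log-rank is invariant under monotone time transforms", {
  d <- random_survival(150, seed = 14)
  g <- rep(1:2, length.out = 150)
  a <- log_rank_test(d$time, d$event, g)
  b <- log_rank_test(log1p(d$time), d$event, g)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
})

test_that("Harrell's C matches the O(n^2) oracle and known endpoints", {
  # perfect ordering, untied event times -> 1
  tt <- 1:6
  expect_equal(harrells_c(rev(tt), tt, rep(1, 6)), 1)
  # brute-force oracle on small random data (with score and time ties)
  for (s in 1:6) {
    set.seed(50 + s)
    n <- if (s <= 3) 10 else 200
    risk <- sample(1:5, n, replace = TRUE)
    time <- sample(1:8, n, replace = TRUE)
    ev <- rbinom(n, 1, 0.6)
    if (sum(ev) == 0) next
    expect_equal(harrells_c(risk, time, ev),
                 oracle_concordance(risk, time, ev), tolerance = 1e-12)
  }
  # random scores at large n are near 1/2
  d <- random_survival(4000, seed = 15)
  set.seed(16)
  expect_equal(harrells_c(rnorm(4000), d$time, d$event), 0.5,
               tolerance = 0.03)
  expect_warning(cc <- harrells_c(1:3, c(1, 1, 1), c(1, 1, 1)),
                 "no usable pairs")
  expect_true(is.na(cc))
})

test_that("Schoenfeld test is calibrated under proportional hazards and powered against violation", {
  # null calibration: p approximately uniform over replicates
  set.seed(17)
  ps <- replicate(150, {
    d <- random_survival(120, seed = sample.int(1e6, 1), beta = 0.5)
    schoenfeld_ph_test(coxph_fit(cbind(x = d$x), d$time, d$event))$p[1]
  })
  expect_gt(mean(ps < 0.05), 0.0)
  expect_lt(mean(ps < 0.05), 0.12)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  # power: a strongly time-varying effect is detected at n = 5000
  set.seed(18)
  n <- 5000
  x <- rnorm(n)
  u <- runif(n)
  # hazard with effect reversing over time: early beta +1, late beta -1
  t1 <- rexp(n, exp(x)); t2 <- 0.3 + rexp(n, exp(-x))
  tm <- ifelse(t1 < 0.3, t1, t2)
  cc <- runif(n, 0, 1.5)
  time <- pmin(tm, cc); ev <- as.integer(tm <= cc)
  p <- schoenfeld_ph_test(coxph_fit(cbind(x = x), time, ev))$p[1]
  expect_lt(p, 1e-4)
  # single-event data: undefined, flagged
  expect_warning(
    r <- schoenfeld_ph_test(
      suppressWarnings(coxph_fit(cbind(x = rnorm(8)), 1:8,
                                 c(1, 1, rep(0, 6))))),
    "undefined")
  expect_true(all(is.na(r$p)))
})

test_that("Holm-Bonferroni matches the hand example and its set inclusions", {
  h <- holm_bonferroni(c(0.01, 0.04, 0.03))
  expect_equal(h$p_adjusted, c(0.03, 0.06, 0.06), tolerance = 1e-12)
  expect_identical(holm_bonferroni(0.02)$p_adjusted, 0.02)
  expect_false(any(holm_bonferroni(rep(1, 5))$reject))
  expect_error(holm_bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
  # agreement with stats::p.adjust and the Bonferroni/raw sandwich
  set.seed(19)
  for (i in 1:20) {
    p <- runif(sample(2:12, 1))
    h <- holm_bonferroni(p)
    expect_equal(h$p_adjusted, stats::p.adjust(p, "holm"),
                 tolerance = 1e-12)
    bonf <- p * length(p) < 0.05
    raw <- p < 0.05
    expect_true(all(h$reject[bonf]))      # Holm >= Bonferroni
    expect_true(all(raw[h$reject]))       # Holm <= unadjusted
  }
})

test_that("subgroup_filter applies the strict LVEF threshold", {
  co <- small_test_cohort(1500, seed = 26)
  co$outcomes$mortality <- simulate_endpoint(co, "mortality",
                                             target_proportion = 0.05,
                                             seed = 13)
  sub <- subgroup_filter(co, 55)
  expect_identical(attr(sub, "n_kept"), sum(co$markers$lvef > 55))
  expect_true(all(sub$markers$lvef > 55))
  expect_identical(nrow(sub$subjects), nrow(sub$markers))
  expect_identical(nrow(sub$outcomes$mortality), nrow(sub$subjects))
  # boundary: exactly at the threshold is excluded
  co2 <- co
  co2$markers$lvef[1] <- 55
  expect_false(1 %in% which(co2$markers$lvef > 55))
  # all above -> identity
  hi <- subgroup_filter(co, 0)
  expect_identical(nrow(hi$subjects), nrow(co$subjects))
})

test_that("marker correlations: symmetry, identities, hand check", {
  co <- small_test_cohort(1200, seed = 27)
  r <- marker_correlations(co$markers)
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 23))
  # functional identity: glase vs glased * lvmv
  expect_equal(stats::cor(co$markers$glase,
                          co$markers$glased * co$measures$lvmv), 1,
               tolerance = 1e-12)
  # 10-row hand (textbook formula) check
  m10 <- co$markers[1:10, c("glased", "lvef")]
  num <- sum((m10$glased - mean(m10$glased)) * (m10$lvef - mean(m10$lvef)))
  den <- sqrt(sum((m10$glased - mean(m10$glased))^2) *
                sum((m10$lvef - mean(m10$lvef))^2))
  expect_equal(marker_correlations(m10)["glased", "lvef"], num / den,
               tolerance = 1e-12)
  expect_error(marker_correlations(co$markers[1:2, ]), "3 subjects")
})

test_that("tertile analysis: sizes, monotone curves, powered log-rank", {
  co <- small_test_cohort(4000, seed = 28)
  co$outcomes$mortality <- simulate_endpoint(
    co, "mortality", marker_log_hr = c(glased = log(2.2)),
    target_proportion = 0.08, seed = 15)
  dat <- survival_data(co, "mortality")
  ta <- tertile_analysis(dat$glased, dat$time, dat$event)
  expect_lte(diff(range(ta$sizes)), 2)
  for (g in 1:3) {
    expect_true(all(diff(ta$curves[[g]]$survival) <= 1e-12))
    expect_true(all(diff(ta$curves[[g]]$cumhaz) >= -1e-12))
  }
  # planted strong effect: lowest-GLASED tertile has the worst survival
  s_end <- vapply(ta$curves, function(k) min(k$survival), 1)
  expect_lt(s_end[1], s_end[3])
  expect_lt(ta$logrank$p, 0.001)
  expect_identical(nrow(ta$logrank$pairwise), 3L)
})
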