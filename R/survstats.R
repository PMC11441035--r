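# Nonparametric survival statistics: Kaplan-Meier product-limit curves,
# tertile splits, the log-rank test (overall and pairwise), Harrell's
# concordance, a Schoenfeld proportional-hazards diagnostic and the
# Holm-Bonferroni step-down correction.

#' Kaplan-Meier product-limit estimate
#'
#' @param times follow-up times.
#' @param events 0/1 event indicators.
#' @param cumhaz `"neg_log"` (default, -log S) or `"nelson_aalen"`.
#' @return object of class `km_fit`: data.frame with one row per distinct
#'   event time (`time`, `n_risk`, `n_event`, `survival`, `cumhaz`).
#'   All-censored input yields S identically 1 with a warning.
#' @export
km_estimate <- function(times, events,
                        cumhaz = c("neg_log", "nelson_aalen")) {
  cumhaz <- match.arg(cumhaz)
  stopifnot(length(times) == length(events), length(times) >= 1)
  if (sum(events) == 0) {
    warning("no events: survival curve is identically 1")
    out <- data.frame(time = numeric(0), n_risk = integer(0),
                      n_event = integer(0), survival = numeric(0),
                      cumhaz = numeric(0))
    class(out) <- c("km_fit", "data.frame")
    return(out)
  }
  ut <- sort(unique(times[events == 1]))
  st <- sort(times)
  n_risk <- length(times) - findInterval(ut, st, left.open = TRUE)
  n_event <- vapply(ut, function(t) sum(times == t & events == 1), 1L)
  surv <- cumprod(1 - n_event / n_risk)
  ch <- switch(cumhaz,
               neg_log = -log(pmax(surv, .Machine$double.xmin)),
               nelson_aalen = cumsum(n_event / n_risk))
  out <- data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                    survival = surv, cumhaz = ch)
  class(out) <- c("km_fit", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param fit a `km_fit`.
#' @param at times at which to evaluate the step function.
#' @return survival probabilities (right-continuous step function; 1
#'   before the first event time).
#' @export
km_survival_at <- function(fit, at) {
  idx <- findInterval(at, fit$time)
  c(1, fit$survival)[idx + 1]
}

#' Split marker values into tertiles
#'
#' Empirical 1/3 and 2/3 quantile cut; values at or below a breakpoint go
#' to the lower tertile, so assignment is deterministic under ties.
#'
#' @param values numeric vector with at least 3 distinct values.
#' @return integer labels 1 (lowest) to 3 (highest), with the breakpoints
#'   as attribute `breakpoints`.
#' @export
tertile_split <- function(values) {
  if (length(unique(values[!is.na(values)])) < 3)
    stop("at least 3 distinct values are required for a tertile split")
  q <- stats::quantile(values, c(1, 2) / 3, na.rm = TRUE, names = FALSE)
  labels <- 1L + (values > q[1]) + (values > q[2])
  attr(labels, "breakpoints") <- q
  labels
}

.logrank_core <- function(times, events, group) {
  glev <- sort(unique(group))
  k <- length(glev)
  ut <- sort(unique(times[events == 1]))
  # per-group numbers at risk and event counts at each distinct event time
  n_risk <- sapply(glev, function(g) {
    sg <- sort(times[group == g])
    length(sg) - findInterval(ut, sg, left.open = TRUE)
  })
  d <- sapply(glev, function(g)
    vapply(ut, function(t) sum(times == t & events == 1 & group == g), 1L))
  n_risk <- matrix(n_risk, ncol = k); d <- matrix(d, ncol = k)
  Nj <- rowSums(n_risk); Dj <- rowSums(d)
  O <- colSums(d)
  E <- colSums(d * 0 + n_risk * (Dj / Nj))
  # hypergeometric variance-covariance, summed over event times
  V <- matrix(0, k, k)
  mult <- Dj * (Nj - Dj) / pmax(Nj - 1, 1)
  pr <- n_risk / Nj
  for (a in seq_len(k)) for (b in seq_len(k)) {
    V[a, b] <- sum(mult * (pr[, a] * ((a == b) - pr[, b])))
  }
  i <- seq_len(k - 1)
  stat <- tryCatch(
    drop(t(O[i] - E[i]) %*% solve(V[i, i, drop = FALSE], (O - E)[i])),
    error = function(e) 0)
  stat <- max(stat, 0)
  list(observed = O, expected = E, statistic = stat, df = k - 1,
       p = stats::pchisq(stat, k - 1, lower.tail = FALSE), groups = glev)
}

#' Log-rank test
#'
#' Standard observed-minus-expected log-rank chi-square over two or more
#' groups (df = groups - 1), plus raw pairwise tests between every group
#' pair.
#'
#' @param times follow-up times.
#' @param events 0/1 event indicators (at least one event overall).
#' @param group group labels (at least 2 groups).
#' @return list of class `logrank_test`: `statistic`, `df`, `p`,
#'   `observed`, `expected`, and `pairwise` (data.frame of group pairs
#'   with statistic and p).
#' @export
log_rank_test <- function(times, events, group) {
  stopifnot(length(times) == length(events), length(group) == length(times))
  glev <- sort(unique(group))
  if (length(glev) < 2) stop("at least 2 groups are required")
  if (sum(events) < 1) stop("at least 1 event is required")
  overall <- .logrank_core(times, events, group)
  pairs <- utils::combn(glev, 2)
  pw <- apply(pairs, 2, function(gp) {
    sel <- group %in% gp
    r <- .logrank_core(times[sel], events[sel], group[sel])
    c(statistic = r$statistic, p = r$p)
  })
  overall$pairwise <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                                 statistic = pw["statistic", ],
                                 p = pw["p", ])
  class(overall) <- "logrank_test"
  overall
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("log-rank test: chi-square %.3f on %d df, p = %.3g\n",
              x$statistic, x$df, x$p))
  invisible(x)
}

#' Kaplan-Meier tertile analysis of one marker
#'
#' Splits a marker into tertiles and computes the per-tertile survival
#' and cumulative-hazard curves with overall and pairwise log-rank tests.
#'
#' @param marker_values numeric marker vector.
#' @param times,events follow-up times and 0/1 indicators.
#' @param cumhaz cumulative-hazard estimator, see [km_estimate()].
#' @return list of class `tertile_analysis`: `breakpoints`, `labels`,
#'   `curves` (list of `km_fit` per tertile), `logrank`.
#' @export
tertile_analysis <- function(marker_values, times, events,
                             cumhaz = c("neg_log", "nelson_aalen")) {
  cumhaz <- match.arg(cumhaz)
  labels <- tertile_split(marker_values)
  curves <- lapply(1:3, function(g)
    km_estimate(times[labels == g], events[labels == g], cumhaz))
  names(curves) <- paste0("tertile", 1:3)
  out <- list(breakpoints = attr(labels, "breakpoints"), labels = labels,
              sizes = tabulate(labels, 3), curves = curves,
              logrank = log_rank_test(times, events, labels))
  class(out) <- "tertile_analysis"
  out
}

#' Harrell's concordance index
#'
#' Event-anchored pairwise concordance: a pair is usable when one subject
#' has an event strictly before the other's observed time; tied event
#' times are excluded, tied risk scores count 1/2.
#'
#' @param risk risk scores (higher = higher hazard).
#' @param times follow-up times.
#' @param events 0/1 event indicators.
#' @return concordance in `[0, 1]`; `NA` with a warning when no usable
#'   pairs exist.
#' @export
harrells_c <- function(risk, times, events) {
  stopifnot(length(risk) == length(times), length(times) == length(events))
  ord <- order(times)
  risk <- risk[ord]; times <- times[ord]; events <- as.integer(events[ord])
  n <- length(risk)
  conc <- disc <- tied <- 0
  for (i in which(events == 1L)) {
    # comparable: strictly later observed time (event or censored)
    j <- which(times > times[i])
    if (!length(j)) next
    conc <- conc + sum(risk[i] > risk[j])
    disc <- disc + sum(risk[i] < risk[j])
    tied <- tied + sum(risk[i] == risk[j])
  }
  tot <- conc + disc + tied
  if (tot == 0) {
    warning("no usable pairs: concordance undefined")
    return(NA_real_)
  }
  (conc + 0.5 * tied) / tot
}

#' Schoenfeld proportional-hazards diagnostic
#'
#' Correlates the scaled Schoenfeld residuals of a fitted Cox model
#' against the rank of event time and reports a 1-df chi-square p-value
#' per covariate, following the Grambsch-Therneau construction with the
#' average information per event.
#'
#' @param fit a low-level fit from [coxph_fit()], or a `cox_result`.
#' @return list with `p` (named per covariate), `chisq`, and the residual
#'   matrix (`residuals`, one row per event, at event times).
#' @export
schoenfeld_ph_test <- function(fit) {
  if (inherits(fit, "cox_result")) fit <- fit$fit
  X <- fit$X; time <- fit$time; event <- fit$event; beta <- fit$beta
  d <- sum(event)
  if (d < 3) {
    warning("fewer than 3 events: Schoenfeld test undefined")
    return(list(p = stats::setNames(rep(NA_real_, ncol(X)), colnames(X)),
                chisq = NULL, residuals = NULL))
  }
  Xc <- sweep(X, 2, colMeans(X))
  w <- exp(drop(Xc %*% beta))
  p <- ncol(X)
  S0 <- .revcumsum(w)
  S1 <- .revcumsum(Xc * w)
  pidx <- .pack_index(p)
  S2 <- .revcumsum(Xc[, pidx[, 1], drop = FALSE] *
                     Xc[, pidx[, 2], drop = FALSE] * w)
  first_at <- match(time, time)
  ev <- which(event == 1L)
  f <- first_at[ev]
  mu <- S1[f, , drop = FALSE] / S0[f]
  resid <- Xc[ev, , drop = FALSE] - mu           # Schoenfeld residuals
  # average per-event covariance of the covariates over the risk sets
  Vbar <- matrix(0, p, p)
  for (i in seq_along(ev))
    Vbar <- Vbar + .unpack_sym(S2[f[i], ] / S0[f[i]], p, pidx) -
      tcrossprod(mu[i, ])
  Vbar <- Vbar / d
  Vinv <- solve(Vbar)
  # scaled residuals s V^-1 (+ beta offset, which centres out of the test)
  scaled <- resid %*% Vinv + matrix(beta, d, p, byrow = TRUE)
  g <- rank(time[ev], ties.method = "average")
  gc <- g - mean(g)
  num <- drop(crossprod(gc, scaled - matrix(colMeans(scaled), d, p,
                                            byrow = TRUE)))
  # Var(sum u_j s*_jk) ~ sum(u^2) (Vbar^-1)_kk when V_j ~ Vbar
  denom <- diag(Vinv) * sum(gc^2)
  chisq <- num^2 / denom
  pvals <- stats::pchisq(chisq, 1, lower.tail = FALSE)
  names(pvals) <- names(chisq) <- colnames(X)
  list(p = pvals, chisq = chisq,
       residuals = structure(resid, time = time[ev]))
}

#' Holm-Bonferroni step-down correction
#'
#' @param p raw p-values in `[0, 1]`.
#' @param alpha family-wise error level for the rejection flags.
#' @return list with `p_adjusted` (monotone step-down adjusted p-values,
#'   in the input order) and `reject` (logical flags at `alpha`).
#' @export
holm_bonferroni <- function(p, alpha = 0.05) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p)
  adj <- pmin(cummax((m - seq_len(m) + 1) * p[ord]), 1)
  out <- numeric(m)
  out[ord] <- adj
  list(p_adjusted = out, reject = out < alpha)
}

#' Filter a cohort to the normal-LVEF subgroup
#'
#' Keeps subjects whose LVEF strictly exceeds the threshold (a subject
#' with LVEF exactly at the threshold is excluded).
#'
#' @param cohort an `lv_cohort`.
#' @param lvef_gt threshold in percent (default 55).
#' @return the filtered `lv_cohort`, with attribute `n_kept`.
#' @export
subgroup_filter <- function(cohort, lvef_gt = 55) {
  stopifnot(inherits(cohort, "lv_cohort"))
  keep <- which(cohort$markers$lvef > lvef_gt)
  out <- cohort
  out$subjects <- cohort$subjects[keep, , drop = FALSE]
  out$measures <- cohort$measures[keep, , drop = FALSE]
  out$markers <- cohort$markers[keep, , drop = FALSE]
  out$outcomes <- lapply(cohort$outcomes, function(o)
    o[keep, , drop = FALSE])
  attr(out, "n_kept") <- length(keep)
  out
}

#' Pairwise Pearson correlations of the marker panel
#'
#' @param panels data.frame of marker columns (>= 3 rows).
#' @return symmetric correlation matrix with unit diagonal; zero-variance
#'   markers give `NA` rows/columns with a warning.
#' @export
marker_correlations <- function(panels) {
  m <- as.matrix(panels[, intersect(marker_names(), names(panels)),
                        drop = FALSE])
  if (nrow(m) < 3) stop("at least 3 subjects are required")
  sds <- apply(m, 2, stats::sd)
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  if (any(sds == 0)) {
    warning(sprintf("zero-variance marker(s): %s",
                    paste(colnames(m)[sds == 0], collapse = ", ")))
    r[sds == 0, ] <- NA; r[, sds == 0] <- NA
  }
  diag(r) <- 1
  r
}
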