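## Survival and group-comparison statistics used by every screening and
## evaluation stage. Conventions, fixed throughout the package:
##   * event = 1 means death observed, 0 means censored;
##   * subjects censored exactly at an event time are counted at risk at
##     that time (standard product-limit convention, stated explicitly so
##     tied fixtures are reproducible to the last digit);
##   * all tests are two-sided and return p-values in (0, 1].

check_survival <- function(time, event) {
  if (length(time) != length(event))
    stop("'time' and 'event' must have equal length", call. = FALSE)
  if (length(time) < 1L) stop("no survival records supplied", call. = FALSE)
  if (any(!is.finite(time)) || any(time <= 0))
    stop("all survival times must be finite and positive", call. = FALSE)
  if (!all(event %in% c(0, 1)))
    stop("'event' must contain only 0 (censored) and 1 (death)", call. = FALSE)
  invisible(TRUE)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function over the distinct event
#' times of a cohort. An input with no observed events yields a curve with no
#' drops, i.e. S(t) = 1 everywhere (query it with [km_survival_at()]).
#'
#' @param time positive follow-up times.
#' @param event event indicators, 1 = death observed, 0 = censored.
#' @return An object of class `km_curve`: a list with `event_times`
#'   (increasing), `survival` (non-increasing, in `[0, 1]`), `at_risk`
#'   (numbers at risk just before each event time), `n_events` (deaths at
#'   each event time) and `n` (cohort size).
#' @seealso [km_survival_at()], [write_km_curve()]
#' @export
km_estimate <- function(time, event) {
  check_survival(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- fit$n.event > 0
  structure(
    list(event_times = fit$time[keep],
         survival = fit$surv[keep],
         at_risk = fit$n.risk[keep],
         n_events = fit$n.event[keep],
         n = length(time)),
    class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Right-continuous step-function lookup: S(t) is the product-limit estimate
#' just after the last event time not exceeding `t`.
#'
#' @param curve a `km_curve` from [km_estimate()].
#' @param times times at which to evaluate the curve.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(curve, times) {
  stopifnot(inherits(curve, "km_curve"))
  if (length(curve$event_times) == 0L) return(rep(1, length(times)))
  idx <- findInterval(times, curve$event_times)
  c(1, curve$survival)[idx + 1L]
}

## Shared observed-minus-expected tabulation for the weighted log-rank family.
## Returns, per distinct event time: total/group-wise numbers at risk and
## deaths. Only relative time order matters, so every statistic built on it is
## invariant under strictly monotone transforms of the time axis.
oe_table <- function(time, event, group) {
  levs <- levels(group)
  ut <- sort(unique(time[event == 1]))
  st <- sort(time)
  n_at <- length(time) - findInterval(ut, st, left.open = TRUE)
  et <- time[event == 1]
  eg <- group[event == 1]
  pos <- match(et, ut)
  d_at <- tabulate(pos, length(ut))
  ng <- length(levs)
  n_g <- matrix(0, length(ut), ng)
  d_g <- matrix(0, length(ut), ng)
  for (k in seq_len(ng)) {
    tg <- sort(time[group == levs[k]])
    n_g[, k] <- length(tg) - findInterval(ut, tg, left.open = TRUE)
    d_g[, k] <- tabulate(pos[eg == levs[k]], length(ut))
  }
  list(times = ut, n = n_at, d = d_at, n_g = n_g, d_g = d_g)
}

## Weighted k-group log-rank-type statistic. weights: one value per distinct
## event time. Uses the hypergeometric mean/covariance at each event time and
## a generalized inverse over the first k-1 groups; the two-group case is
## fully vectorized.
weighted_logrank <- function(time, event, group, weights) {
  tab <- oe_table(time, event, group)
  ng <- ncol(tab$n_g)
  k <- length(tab$times)
  if (k == 0L) stop("no observed events; test undefined", call. = FALSE)
  if (ng == 2L) {
    n <- tab$n; d <- tab$d; n1 <- tab$n_g[, 1]
    U <- sum(weights * (tab$d_g[, 1] - n1 * d / n))
    v <- ifelse(n > 1, d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1), 0)
    V <- sum(weights^2 * v)
    chi2 <- if (V > 0) U^2 / V else 0
    return(list(chi2 = chi2, df = 1L,
                p = max(stats::pchisq(chi2, 1, lower.tail = FALSE),
                        .Machine$double.xmin)))
  }
  U <- numeric(ng - 1L)
  V <- matrix(0, ng - 1L, ng - 1L)
  for (i in seq_len(k)) {
    n <- tab$n[i]; d <- tab$d[i]; w <- weights[i]
    e <- tab$n_g[i, ] * d / n
    U <- U + w * (tab$d_g[i, -ng] - e[-ng])
    if (n > 1) {
      p <- tab$n_g[i, -ng] / n
      vi <- d * (n - d) / (n - 1) * (diag(p, nrow = ng - 1L) - tcrossprod(p))
      V <- V + w^2 * vi
    }
  }
  Vi <- tryCatch(solve(V), error = function(e) MASS_ginv(V))
  chi2 <- max(0, drop(t(U) %*% Vi %*% U))
  df <- ng - 1L
  list(chi2 = chi2, df = df, p = max(stats::pchisq(chi2, df, lower.tail = FALSE),
                                     .Machine$double.xmin))
}

## Moore-Penrose generalized inverse (needed only when the hypergeometric
## covariance is singular, e.g. a group exhausted before the first event).
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > tol * s$d[1]
  if (!any(pos)) return(matrix(0, ncol(X), nrow(X)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Log-rank test
#'
#' Observed-minus-expected test over distinct event times with hypergeometric
#' variance (unit weights); for `k` groups the statistic is chi-square with
#' `k - 1` degrees of freedom. Depends only on the ordering of the times, so
#' it is invariant under strictly monotone time transforms.
#'
#' @param time,event survival data as in [km_estimate()].
#' @param group group labels (>= 2 non-empty groups).
#' @return list with `chi2`, `df` and `p`.
#' @export
logrank_test <- function(time, event, group) {
  check_survival(time, event)
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2L)
    stop("log-rank test needs at least two non-empty groups", call. = FALSE)
  tab_times <- sort(unique(time[event == 1]))
  weighted_logrank(time, event, group, rep(1, length(tab_times)))
}

#' Gehan-Breslow generalized Wilcoxon test
#'
#' Same observed-minus-expected tabulation as the log-rank test but each
#' distinct event time is weighted by the total number at risk at that time,
#' emphasising early survival differences. Two groups only; 1 df chi-square.
#'
#' @inheritParams logrank_test
#' @return list with `chi2`, `df` and `p`.
#' @export
gehan_wilcoxon_test <- function(time, event, group) {
  check_survival(time, event)
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L)
    stop("Gehan-Wilcoxon test is defined here for exactly two groups", call. = FALSE)
  ut <- sort(unique(time[event == 1]))
  w <- vapply(ut, function(t) sum(time >= t), numeric(1))
  weighted_logrank(time, event, group, w)
}

#' Univariable Cox fit for a binary covariate
#'
#' Maximum partial likelihood for a single binary covariate with Efron
#' handling of tied event times (via `survival::coxph`). Complete separation
#' of the event ordering is flagged as non-converged with the log hazard
#' ratio capped at |beta| <= 20.
#'
#' @inheritParams logrank_test
#' @param x binary covariate (0/1, or any two-level vector); both levels must
#'   be present.
#' @return An object of class `cox_fit`: list with `beta` (log hazard ratio
#'   of level 2 vs level 1), `hr = exp(beta)`, `se`, `p_wald` (two-sided
#'   normal), `ci95` (Wald), `converged` and `n_events`.
#' @export
cox_binary <- function(time, event, x) {
  check_survival(time, event)
  xf <- as.factor(x)
  if (nlevels(droplevels(xf)) != 2L)
    stop("covariate must take exactly two values in the data", call. = FALSE)
  if (sum(event) < 1L) stop("no observed events; Cox fit undefined", call. = FALSE)
  xi <- as.numeric(droplevels(xf)) - 1
  ## low-level fitter (identical to coxph(..., ties = "efron") but without
  ## model-frame overhead; this runs tens of thousands of times per screen)
  maybe_infinite <- FALSE
  fit <- withCallingHandlers(
    survival::coxph.fit(matrix(xi, ncol = 1),
                        survival::Surv(time, as.numeric(event)),
                        strata = NULL, offset = NULL, init = 0,
                        control = survival::coxph.control(),
                        weights = NULL, method = "efron",
                        rownames = NULL),
    warning = function(w) {
      maybe_infinite <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(fit$coefficients)
  se <- sqrt(unname(fit$var[1]))
  converged <- is.finite(beta) && is.finite(se) && abs(beta) <= 20 &&
    !maybe_infinite
  if (!is.finite(beta)) beta <- 0
  if (abs(beta) > 20) beta <- sign(beta) * 20
  p <- if (is.finite(se) && se > 0)
    max(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin) else 1
  structure(
    list(beta = beta, hr = exp(beta), se = se, p_wald = p,
         ci95 = exp(beta + c(-1, 1) * 1.96 * se),
         converged = converged, n_events = sum(event)),
    class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox fit (binary, Efron ties): HR = %.4g [%.4g, %.4g], p_wald = %.3g, events = %d%s\n",
              x$hr, x$ci95[1], x$ci95[2], x$p_wald, x$n_events,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Time-dependent ROC curve at a fixed horizon
#'
#' Cumulative-case / dynamic-control ROC at follow-up horizon `t`: cases are
#' subjects with an event by `t`, controls are subjects still event-free at
#' `t`. Case and control probabilities at each marker threshold are estimated
#' with Kaplan-Meier curves fitted within the marker strata (the smoothing-free
#' variant, appropriate for discrete markers such as an integer risk score).
#' Each distinct marker value acts as one threshold; the resulting operating
#' points are clipped to `[0, 1]` and monotonized before the trapezoidal AUC
#' is computed, so the emitted curve is always a valid ROC.
#'
#' @inheritParams logrank_test
#' @param marker numeric risk marker (higher = higher risk).
#' @param horizon evaluation time, within the observed time range.
#' @return An object of class `td_roc_curve`: list with `horizon`,
#'   `thresholds` (decreasing), `sensitivity`, `one_minus_specificity`
#'   (both non-decreasing along the emitted thresholds) and `auc`.
#' @export
td_roc <- function(marker, time, event, horizon) {
  check_survival(time, event)
  if (length(marker) != length(time))
    stop("'marker' must align with the survival data", call. = FALSE)
  if (any(!is.finite(marker))) stop("'marker' must be finite", call. = FALSE)
  if (horizon <= 0 || horizon > max(time))
    stop("'horizon' must lie within the observed time range", call. = FALSE)
  s_all <- km_survival_at(km_estimate(time, event), horizon)
  if (1 - s_all <= 0)
    stop("no cases by the horizon: event probability is zero", call. = FALSE)
  if (s_all <= 0)
    stop("no controls at the horizon: survival probability is zero", call. = FALSE)
  thr <- sort(unique(marker), decreasing = TRUE)
  sens <- numeric(length(thr))
  oms <- numeric(length(thr))
  for (i in seq_along(thr)) {
    sel <- marker >= thr[i]
    p_sel <- mean(sel)
    s_sel <- km_survival_at(km_estimate(time[sel], event[sel]), horizon)
    sens[i] <- (1 - s_sel) * p_sel / (1 - s_all)
    oms[i] <- s_sel * p_sel / s_all
  }
  sens <- cummax(pmin(pmax(sens, 0), 1))
  oms <- cummax(pmin(pmax(oms, 0), 1))
  xs <- c(0, oms, 1)
  ys <- c(0, sens, 1)
  auc <- sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
  structure(
    list(horizon = horizon, thresholds = thr, sensitivity = sens,
         one_minus_specificity = oms, auc = auc),
    class = "td_roc_curve")
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t statistic with Satterthwaite degrees of freedom. The
#' degenerate case of two zero-variance groups is handled explicitly: equal
#' means give p = 1, unequal means a capped statistic with vanishing p.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @return list with `t`, `df`, `p`, `mean_x`, `mean_y`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least two observations", call. = FALSE)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1,
                  mean_x = mean(x), mean_y = mean(y)))
    return(list(t = sign(mean(x) - mean(y)) * 1e8,
                df = length(x) + length(y) - 2, p = .Machine$double.xmin,
                mean_x = mean(x), mean_y = mean(y)))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = max(ht$p.value, .Machine$double.xmin),
       mean_x = mean(x), mean_y = mean(y))
}

#' Two-tailed paired t-test
#'
#' One-sample t-test on the within-pair differences. All-zero differences
#' give p = 1; constant non-zero differences a capped statistic with
#' vanishing p.
#'
#' @param x,y paired numeric samples of equal length >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length", call. = FALSE)
  if (length(x) < 2L) stop("need at least two pairs", call. = FALSE)
  d <- x - y
  if (stats::var(d) == 0) {
    if (all(d == 0)) return(list(t = 0, df = length(d) - 1, p = 1))
    return(list(t = sign(mean(d)) * 1e8, df = length(d) - 1,
                p = .Machine$double.xmin))
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = max(ht$p.value, .Machine$double.xmin))
}
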