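# Independent brute-force oracles. These re-derive each statistic from its
# defining formula by direct enumeration, deliberately sharing no code with
# the package implementations they check.

# Product-limit estimator by explicit per-event-time looping.
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  surv <- numeric(length(ut))
  at_risk <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    n_i <- sum(time >= ut[i])
    d_i <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d_i / n_i)
    surv[i] <- s
    at_risk[i] <- n_i
  }
  list(event_times = ut, survival = surv, at_risk = at_risk)
}

# Two-group weighted O/E/V tabulation; weight_fun maps number-at-risk to the
# event-time weight (1 for log-rank, identity for Gehan).
oracle_weighted_logrank <- function(time, event, group, weight_fun = function(n) 1) {
  g1 <- sort(unique(group))[1]
  ut <- sort(unique(time[event == 1]))
  num <- 0; den <- 0
  for (t in ut) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    w <- weight_fun(n)
    num <- num + w * (d1 - n1 * d / n)
    if (n > 1)
      den <- den + w^2 * d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (den > 0) num^2 / den else 0
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

# Efron-approximation partial log-likelihood for one binary covariate.
oracle_efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    s_r <- sum(exp(beta * x[R]))
    s_d <- sum(exp(beta * x[D]))
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d) - 1) ll <- ll - log(s_r - (l / d) * s_d)
  }
  ll
}

# Two-stage grid search maximizing the Efron partial likelihood to 1e-6.
oracle_efron_beta <- function(time, event, x, lim = 5) {
  grid <- seq(-lim, lim, by = 0.01)
  ll <- vapply(grid, oracle_efron_loglik, numeric(1), time = time,
               event = event, x = x)
  b0 <- grid[which.max(ll)]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-6)
  llf <- vapply(fine, oracle_efron_loglik, numeric(1), time = time,
                event = event, x = x)
  fine[which.max(llf)]
}

oracle_welch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

oracle_paired <- function(x, y) {
  d <- x - y
  t <- mean(d) / (sd(d) / sqrt(length(d)))
  list(t = t, p = 2 * pt(-abs(t), length(d) - 1))
}

# Mann-Whitney AUC with ties counted one-half.
oracle_auc <- function(marker, is_case) {
  mc <- marker[is_case]; mn <- marker[!is_case]
  tot <- 0
  for (a in mc) tot <- tot + sum(a > mn) + 0.5 * sum(a == mn)
  tot / (length(mc) * length(mn))
}

# Small random censored survival fixtures with ties.
random_surv_fixture <- function(n, seed, tie_grid = 6) {
  set.seed(seed)
  list(time = sample(tie_grid, n, replace = TRUE) + 0.5,
       event = rbinom(n, 1, 0.7),
       group = factor(rbinom(n, 1, 0.5)))
}
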