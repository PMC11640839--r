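test_that("Kaplan-Meier estimator matches the product-limit oracle and the empirical survival", {
  # no censoring: S equals the empirical survival at each event time
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2/3, 1/3, 0))
  expect_equal(km$at_risk, c(3, 2, 1))

  # all censored: constant curve S == 1
  km0 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_length(km0$event_times, 0)
  expect_equal(km_survival_at(km0, c(0.5, 2, 10)), c(1, 1, 1))

  # hand product-limit with censoring: (1, 2+, 3) -> S(1)=2/3, S(3)=0
  km1 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km1$survival, c(2/3, 0))
  expect_equal(km_survival_at(km1, c(1, 2.5, 3)), c(2/3, 2/3, 0))

  # random tied/censored fixtures against the oracle
  for (seed in 1:5) {
    f <- random_surv_fixture(20, seed)
    got <- km_estimate(f$time, f$event)
    want <- oracle_km(f$time, f$event)
    expect_equal(got$event_times, want$event_times)
    expect_equal(got$survival, want$survival, tolerance = 1e-12)
    expect_equal(as.numeric(got$at_risk), want$at_risk)
  }
})

test_that("log-rank and Gehan-Wilcoxon match brute-force O/E/V tabulations and survdiff", {
  for (seed in 1:8) {
    f <- random_surv_fixture(18, seed)
    if (nlevels(droplevels(f$group)) < 2 || sum(f$event) == 0) next
    lr <- logrank_test(f$time, f$event, f$group)
    gw <- gehan_wilcoxon_test(f$time, f$event, f$group)
    expect_equal(lr$chi2,
                 oracle_weighted_logrank(f$time, f$event, f$group)$chi2,
                 tolerance = 1e-10)
    expect_equal(gw$chi2,
                 oracle_weighted_logrank(f$time, f$event, f$group,
                                         weight_fun = identity)$chi2,
                 tolerance = 1e-10)
    sd <- survival::survdiff(survival::Surv(f$time, f$event) ~ f$group)
    expect_equal(lr$chi2, unname(sd$chisq), tolerance = 1e-10)
  }
})

test_that("log-rank degenerate and symmetric cases behave as the formula dictates", {
  # two groups that are identical copies of one sample set
  tt <- c(1, 2, 3, 4.5, 6); ev <- c(1, 0, 1, 1, 0)
  lr <- logrank_test(c(tt, tt), c(ev, ev), rep(c("a", "b"), each = 5))
  expect_equal(lr$chi2, 0)
  expect_equal(lr$p, 1)
  gw <- gehan_wilcoxon_test(c(tt, tt), c(ev, ev), rep(c("a", "b"), each = 5))
  expect_equal(gw$chi2, 0)

  # a single distinct event time: the at-risk weight cancels, p identical
  t1 <- c(3, 3, 3, 5, 6, 7); e1 <- c(1, 1, 1, 0, 0, 0)
  g1 <- c("a", "a", "b", "a", "b", "b")
  expect_equal(gehan_wilcoxon_test(t1, e1, g1)$p, logrank_test(t1, e1, g1)$p,
               tolerance = 1e-12)

  expect_error(logrank_test(c(1, 2), c(1, 1), c("a", "a")), "two")
  expect_error(gehan_wilcoxon_test(c(1, 2), c(1, 1), c("a", "a")), "two")
})

test_that("weighted survival tests are invariant under monotone time transforms", {
  transforms <- list(function(t) t^2, function(t) exp(t) - 0.5,
                     function(t) log(1 + t) + 0.01 * t)
  for (seed in 1:4) {
    f <- random_surv_fixture(25, seed)
    lr0 <- logrank_test(f$time, f$event, f$group)
    gw0 <- gehan_wilcoxon_test(f$time, f$event, f$group)
    for (tr in transforms) {
      expect_equal(logrank_test(tr(f$time), f$event, f$group)$chi2, lr0$chi2,
                   tolerance = 1e-12)
      expect_equal(gehan_wilcoxon_test(tr(f$time), f$event, f$group)$chi2,
                   gw0$chi2, tolerance = 1e-12)
    }
  }
})

test_that("binary Cox fit maximizes the Efron partial likelihood", {
  # 12-subject fixture with tied event times
  tt <- c(1, 1, 2, 2, 2, 3, 4, 4, 5, 6, 7, 8)
  ev <- c(1, 1, 1, 0, 1, 1, 1, 1, 0, 1, 0, 1)
  x <- c(1, 0, 1, 1, 0, 1, 0, 1, 0, 0, 1, 0)
  fit <- cox_binary(tt, ev, x)
  expect_lt(abs(fit$beta - oracle_efron_beta(tt, ev, x)), 1e-4)
  expect_equal(fit$hr, exp(fit$beta))
  expect_equal(fit$p_wald, 2 * pnorm(-abs(fit$beta / fit$se)))

  # random tied fixtures
  for (seed in 1:4) {
    f <- random_surv_fixture(15, seed + 50)
    x <- as.numeric(f$group) - 1
    if (length(unique(x)) < 2 || sum(f$event) < 2) next
    fit <- cox_binary(f$time, f$event, x)
    if (!fit$converged) next
    expect_lt(abs(fit$beta - oracle_efron_beta(f$time, f$event, x)), 1e-4)
  }
})

test_that("binary Cox fit handles null, separated and degenerate inputs", {
  # label independent of outcome at large n: hr within 3 SE of 1
  set.seed(11)
  n <- 1500
  tt <- rexp(n); ev <- rbinom(n, 1, 0.8); x <- rbinom(n, 1, 0.5)
  fit <- cox_binary(tt, ev, x)
  expect_lt(abs(fit$beta), 3 * fit$se)

  # complete separation in the event ordering: flagged, |beta| capped
  ts <- c(1, 2, 3, 4, 10, 11, 12, 13)
  fit_sep <- cox_binary(ts, rep(1, 8), c(1, 1, 1, 1, 0, 0, 0, 0))
  expect_false(fit_sep$converged)
  expect_lte(abs(fit_sep$beta), 20)

  expect_error(cox_binary(c(1, 2, 3, 4), c(0, 0, 0, 0), c(0, 1, 0, 1)), "event")
  expect_error(cox_binary(c(1, 2), c(1, 1), c(1, 1)), "two")
})

test_that("binary Cox fit recovers a planted two-group hazard ratio", {
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    n <- 2000
    x <- rbinom(n, 1, 0.5)
    tt <- rexp(n, 0.1 * 2^x)
    fit <- cox_binary(tt, rep(1, n), x)
    if (fit$hr > 1.8 && fit$hr < 2.2) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("time-dependent ROC reduces to the Mann-Whitney AUC without censoring", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 40
    marker <- sample(0:4, n, replace = TRUE)    # discrete, with ties
    tt <- rexp(n, 0.2 * exp(0.5 * marker))
    horizon <- median(tt)
    roc <- td_roc(marker, tt, rep(1, n), horizon)
    expect_equal(roc$auc, oracle_auc(marker, tt <= horizon), tolerance = 1e-10)
  }

  # perfect marker: higher marker always dies earlier
  tt <- c(5, 4, 3, 2, 1)
  expect_equal(td_roc(1:5, tt, rep(1, 5), 2.5)$auc, 1.0)
  # constant marker: the diagonal
  expect_equal(td_roc(rep(2, 20), rexp(20, 1) + 0.1, rep(1, 20), 0.5)$auc, 0.5)
})

test_that("time-dependent ROC is censoring-aware, monotone, and errors on degenerate horizons", {
  set.seed(3)
  n <- 120
  marker <- rnorm(n)
  t_ev <- rexp(n, 0.3 * exp(0.8 * marker))
  t_cn <- runif(n, 0, 6)
  tt <- pmin(t_ev, t_cn); ev <- as.integer(t_ev <= t_cn)
  roc <- td_roc(marker, tt, ev, 2)
  expect_true(all(diff(roc$sensitivity) >= 0))
  expect_true(all(diff(roc$one_minus_specificity) >= 0))
  expect_gt(roc$auc, 0.5)   # marker is genuinely prognostic here
  expect_lte(roc$auc, 1)

  # monotone marker transforms leave the curve unchanged
  roc2 <- td_roc(exp(2 * marker), tt, ev, 2)
  expect_equal(roc2$auc, roc$auc, tolerance = 1e-12)
  expect_equal(roc2$sensitivity, roc$sensitivity, tolerance = 1e-12)

  # no cases before a tiny horizon
  expect_error(td_roc(marker, tt + 10, ev, 1), "no cases")
  # no controls: everyone dead well before the horizon
  expect_error(td_roc(1:6, c(1, 1, 2, 2, 3, 3), rep(1, 6), 3), "no controls")
})

test_that("Welch and paired t statistics match the textbook formulas", {
  x <- c(3.1, 4.2, 2.8, 5.0, 3.3)
  y <- c(6.4, 5.9, 7.1, 6.0, 8.2)
  got <- welch_t(x, y)
  want <- oracle_welch(x, y)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$df, want$df, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)

  set.seed(9)
  a <- rnorm(8); b <- a + rnorm(8, 0.5)
  gp <- paired_t(a, b)
  wp <- oracle_paired(a, b)
  expect_equal(gp$t, wp$t, tolerance = 1e-12)
  expect_equal(gp$p, wp$p, tolerance = 1e-12)

  # degenerate cases
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(welch_t(c(2, 2), c(2, 2))$p, 1)
  expect_lt(welch_t(c(2, 2), c(3, 3))$p, 1e-10)
  expect_equal(paired_t(a, a)$t, 0)
  expect_equal(paired_t(a, a)$p, 1)
  expect_lt(paired_t(a, a + 1)$p, 1e-10)
})

test_that("all survival tests emit p-values in (0, 1]", {
  for (seed in 1:6) {
    f <- random_surv_fixture(30, seed + 100)
    ps <- c(logrank_test(f$time, f$event, f$group)$p,
            gehan_wilcoxon_test(f$time, f$event, f$group)$p,
            cox_binary(f$time, f$event, as.numeric(f$group) - 1)$p_wald,
            welch_t(rnorm(5), rnorm(5))$p,
            paired_t(rnorm(5), rnorm(5))$p)
    expect_true(all(ps > 0 & ps <= 1))
  }
})
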