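fake_scores <- function(score, ids = sprintf("s%03d", seq_along(score)),
                        threshold = 3L) {
  structure(data.frame(sample_id = ids, score = score,
                       k_available = 4L,
                       group = ifelse(score >= threshold, "high", "low"),
                       stringsAsFactors = FALSE),
            class = c("risk_scores", "data.frame"), threshold = threshold)
}

test_that("KM-by-risk needs two occupied levels and detects identical groups", {
  set.seed(1)
  cl <- data.frame(sample_id = sprintf("s%03d", 1:40),
                   os_time = rexp(40) + 0.05, os_event = rbinom(40, 1, 0.8))
  expect_error(km_by_risk(fake_scores(rep(0, 40)), cl), "one occupied")

  # two risk levels carrying identical survival data: log-rank p = 1
  tt <- rexp(20) + 0.1; ev <- rbinom(20, 1, 0.8)
  cl2 <- data.frame(sample_id = sprintf("s%03d", 1:40),
                    os_time = c(tt, tt), os_event = c(ev, ev))
  out <- km_by_risk(fake_scores(rep(c(0, 4), each = 20)), cl2)
  expect_equal(out$chi2, 0, tolerance = 1e-12)
  expect_equal(out$p, 1)
  expect_named(out$curves, c("score_0", "score_4"))
})

test_that("KM curves order by risk score when pair effects are planted", {
  ordered <- 0
  for (seed in 1:20) {
    cfg <- planted_cohort_config(seed + 300, "S", n_per_batch = 250,
                                 n_genes = 30)
    sim <- simulate_cohort(cfg)
    sig <- pair_signature(sim$truth$planted_pair_ids$upg,
                          sim$truth$planted_pair_ids$fpg)
    sc <- score_samples(sig, sim$expression[[1]])
    out <- tryCatch(km_by_risk(sc, sim$clinical), error = function(e) NULL)
    if (is.null(out)) next
    lev <- as.numeric(sub("score_", "", names(out$curves)))
    h <- min(vapply(out$curves, function(cv)
      max(cv$event_times[1], 1e-9), numeric(1)))
    horizon <- 2
    s_at <- vapply(out$curves, km_survival_at, numeric(1), times = horizon)
    if (s_at[which.min(lev)] > s_at[which.max(lev)]) ordered <- ordered + 1
  }
  expect_gte(ordered, 18)
})

test_that("stratified evaluation reports non-evaluable strata and finds within-stratum effects", {
  # a stratum holding only low-risk samples must not crash
  set.seed(2)
  cl <- data.frame(sample_id = sprintf("s%03d", 1:60),
                   os_time = rexp(60) + 0.1, os_event = rbinom(60, 1, 0.7),
                   ipi_group = rep(c("low", "high"), each = 30))
  sc <- fake_scores(c(rep(0, 30), sample(0:4, 30, TRUE)))
  out <- stratified_eval(sc, cl, "ipi_group")
  expect_false(out$low$evaluable)
  expect_error(stratified_eval(sc, cl, "nonexistent"), "unknown")

  # planted within-stratum effect, log-HR log(2.5): all strata significant
  set.seed(3)
  n <- 1500
  strat <- rep(c("GCB", "ABC", "UNC"), each = n / 3)
  grp <- rbinom(n, 1, 0.45)
  tt <- rexp(n, 0.2 * 2.5^grp)
  cl2 <- data.frame(sample_id = sprintf("t%04d", 1:n), os_time = tt,
                    os_event = 1L, coo = strat)
  sc2 <- fake_scores(ifelse(grp == 1, 4, 0), ids = cl2$sample_id)
  out2 <- stratified_eval(sc2, cl2, "coo")
  expect_true(all(vapply(out2, function(s) s$evaluable, logical(1))))
  expect_true(all(vapply(out2, function(s) s$p, numeric(1)) < 0.05))
})

test_that("stratified p-values are uniform under risk-label permutation", {
  set.seed(4)
  n <- 120
  cl <- data.frame(sample_id = sprintf("s%03d", 1:n),
                   os_time = rexp(n) + 0.02, os_event = rbinom(n, 1, 0.75),
                   myc = rep("normal", n))
  base_score <- rep(c(0, 4), each = n / 2)
  ps <- vapply(1:300, function(i) {
    set.seed(1000 + i)
    sc <- fake_scores(sample(base_score), ids = cl$sample_id)
    stratified_eval(sc, cl, "myc")$normal$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("linear signature scores are linear and tolerate missing genes", {
  set.seed(5)
  x <- matrix(rnorm(12), 3, 4,
              dimnames = list(c("A", "B", "C"), paste0("s", 1:4)))
  sig <- data.frame(gene = c("A", "B"), coefficient = c(0, 0))
  expect_equal(unname(linear_score(sig, x)), rep(0, 4))

  one <- data.frame(gene = "B", coefficient = 1)
  expect_equal(linear_score(one, x), x["B", ])

  two <- data.frame(gene = c("A", "C"), coefficient = c(1.5, -2))
  expect_equal(linear_score(transform(two, coefficient = -coefficient), x),
               -linear_score(two, x))

  partial <- data.frame(gene = c("A", "ZZZ"), coefficient = c(2, 9))
  expect_message(got <- linear_score(partial, x), "coverage")
  expect_equal(got, 2 * x["A", ])
  expect_error(linear_score(data.frame(gene = "ZZZ", coefficient = 1), x),
               "none of the signature genes")
})

test_that("mean 1-3y AUC composes the per-horizon ROC AUCs", {
  set.seed(6)
  n <- 150
  marker <- rnorm(n)
  t_ev <- rexp(n, 0.25 * exp(0.7 * marker))
  t_cn <- runif(n, 0, 8)
  cl <- data.frame(sample_id = sprintf("s%03d", 1:n),
                   os_time = pmin(t_ev, t_cn),
                   os_event = as.integer(t_ev <= t_cn))
  out <- signature_auc(marker, cl, horizons = c(1, 2, 3))
  per <- vapply(c(1, 2, 3), function(h)
    td_roc(marker, cl$os_time, cl$os_event, h)$auc, numeric(1))
  expect_equal(unname(out$auc), per)
  expect_equal(out$mean_auc, mean(per))

  # perfect and constant markers
  tt <- sort(rexp(30) + 0.1, decreasing = TRUE)
  clp <- data.frame(sample_id = paste0("p", 1:30), os_time = tt, os_event = 1L)
  expect_equal(signature_auc(1:30, clp, horizons = median(tt))$mean_auc, 1)
  expect_equal(signature_auc(rep(1, 30), clp, horizons = median(tt))$mean_auc, 0.5)

  # degenerate horizon excluded with a warning
  expect_warning(deg <- signature_auc(marker, cl, horizons = c(2, 1e-6)),
                 "excluded")
  expect_true(is.na(deg$auc[2]))
  expect_equal(deg$mean_auc, unname(deg$auc[1]))
})

test_that("signature ranking uses min-tie ranks and two-decimal mean ranks", {
  auc <- rbind(a = c(0.80, 0.70, 0.90),
               b = c(0.80, 0.60, 0.85),
               c = c(0.75, 0.75, 0.95))
  colnames(auc) <- paste0("d", 1:3)
  rt <- rank_signatures(auc)
  expect_equal(unname(rt$ranks["a", ]), c(1, 2, 2))   # tie with b shares rank 1
  expect_equal(unname(rt$ranks["b", ]), c(1, 3, 3))
  expect_equal(unname(rt$ranks["c", ]), c(3, 1, 1))
  expect_equal(unname(rt$mean_rank[["a"]]), round(mean(c(1, 2, 2)), 2))

  # a signature strictly best everywhere has mean rank 1.00
  best <- rbind(win = c(0.9, 0.9), other = c(0.5, 0.6))
  expect_equal(unname(rank_signatures(best)$mean_rank[["win"]]), 1)

  expect_error(rank_signatures(rbind(c(1, NA))), "missing")
  expect_error(summarize_rank_table(rbind(c(1, NA))), "missing")
})

test_that("mean ranks stay bounded and average to (k+1)/2 without ties", {
  set.seed(8)
  for (i in 1:5) {
    k <- sample(4:10, 1); d <- sample(3:8, 1)
    auc <- matrix(runif(k * d), k, d,
                  dimnames = list(paste0("sig", 1:k), paste0("ds", 1:d)))
    rt <- rank_signatures(auc)
    expect_true(all(rt$mean_rank >= 1 & rt$mean_rank <= k))
    expect_equal(mean(rt$mean_rank), (k + 1) / 2, tolerance = 0.01)
  }
})
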