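## Synthetic multi-batch expression cohorts with survival outcomes, planted
## prognostic genes and gene-pairs, and synthetic cell-line drug panels.
## These emulate the *structure* of merged DLBCL microarray cohorts (batches
## with additive/multiplicative effects, a minority of survival-associated
## genes, exponential baseline hazard with independent censoring, regimen
## labels), not any particular real dataset.

#' Simulation configuration
#'
#' Validates and assembles the parameters of [simulate_cohort()].
#'
#' Expression for gene g, sample j in batch b is
#' `mu_g + gamma_{g,b} + delta_{g,b} * eps_{g,j}` with
#' `eps ~ N(0, noise_sd)`, `gamma ~ N(0, batch_shift_sd)` and
#' `delta = exp(N(0, batch_scale_sd))`. The hazard of sample j is
#' `baseline_hazard * exp(sum_g beta_g z_g + sum_p pair_log_hr * s_p)` where
#' `z_g` is the above-cohort-median indicator of the batch-free expression
#' (`mu + eps`), `beta_g = +gene_log_hr` for planted unfavorable genes and
#' `-gene_log_hr` for planted favorable genes, and `s_p` is the binary pair
#' indicator computed from the quantile-transformed batch-free expression.
#' Survival times are exponential with that hazard; censoring is uniform on
#' `(0, c)` with `c` solved numerically so the expected censored fraction
#' equals `censor_rate_target`.
#'
#' @param n_genes number of genes.
#' @param n_samples_per_batch integer vector, samples per batch (each >= 2).
#' @param n_fpg_planted,n_upg_planted numbers of planted favorable /
#'   unfavorable prognostic genes (disjoint sets).
#' @param gene_log_hr magnitude of the per-gene log hazard ratio of the
#'   dichotomized planted genes (sign fixed by class).
#' @param planted_pairs two-column matrix (or list of length-2 vectors) of
#'   indices `(upg index, fpg index)` into the planted UPG / FPG sets.
#' @param pair_log_hr log hazard ratio added per active planted-pair
#'   indicator.
#' @param baseline_hazard events per time unit (time unit: years throughout
#'   the package defaults).
#' @param censor_rate_target target censored fraction, in `[0, 1)`.
#' @param batch_shift_sd,batch_scale_sd SDs of the additive and
#'   log-multiplicative per-gene batch effects.
#' @param noise_sd SD of the biological/technical residual (> 0).
#' @param regimen_mix named fractions over `c(CHOP, R-CHOP, other)`, summing
#'   to 1.
#' @param id_prefix prefix for sample ids (use distinct prefixes when
#'   simulating several cohorts to keep sample ids globally unique).
#' @param seed integer seed; fixed seed gives bitwise-identical cohorts.
#' @return An object of class `sim_config` (validated list).
#' @export
sim_config <- function(n_genes = 500L,
                       n_samples_per_batch = c(200L, 200L),
                       n_fpg_planted = 0L, n_upg_planted = 0L,
                       gene_log_hr = log(2.5),
                       planted_pairs = NULL, pair_log_hr = log(2.2),
                       baseline_hazard = 0.15,
                       censor_rate_target = 0.3,
                       batch_shift_sd = 0, batch_scale_sd = 0,
                       noise_sd = 1,
                       regimen_mix = c(CHOP = 0.2, `R-CHOP` = 0.7, other = 0.1),
                       id_prefix = "S", seed = 1L) {
  stopifnot(n_genes >= 1, length(n_samples_per_batch) >= 1)
  if (any(n_samples_per_batch < 2))
    stop("every batch needs at least two samples", call. = FALSE)
  if (n_fpg_planted < 0 || n_upg_planted < 0 ||
      n_fpg_planted + n_upg_planted > n_genes)
    stop("planted gene counts must be non-negative and fit in 'n_genes'", call. = FALSE)
  if (censor_rate_target < 0 || censor_rate_target >= 1)
    stop("'censor_rate_target' must lie in [0, 1)", call. = FALSE)
  if (batch_shift_sd < 0 || batch_scale_sd < 0 || noise_sd <= 0)
    stop("batch-effect SDs must be >= 0 and 'noise_sd' > 0", call. = FALSE)
  if (!setequal(names(regimen_mix), c("CHOP", "R-CHOP", "other")) ||
      any(regimen_mix < 0) || abs(sum(regimen_mix) - 1) > 1e-8)
    stop("'regimen_mix' must be fractions over CHOP/R-CHOP/other summing to 1",
         call. = FALSE)
  if (!is.null(planted_pairs)) {
    if (is.list(planted_pairs)) planted_pairs <- do.call(rbind, planted_pairs)
    planted_pairs <- matrix(as.integer(planted_pairs), ncol = 2)
    if (any(planted_pairs[, 1] < 1) || any(planted_pairs[, 1] > n_upg_planted) ||
        any(planted_pairs[, 2] < 1) || any(planted_pairs[, 2] > n_fpg_planted))
      stop("'planted_pairs' indices must point into the planted UPG/FPG sets",
           call. = FALSE)
    if (anyDuplicated(planted_pairs))
      stop("duplicated planted pairs", call. = FALSE)
  }
  structure(list(
    n_genes = as.integer(n_genes),
    n_samples_per_batch = as.integer(n_samples_per_batch),
    n_fpg_planted = as.integer(n_fpg_planted),
    n_upg_planted = as.integer(n_upg_planted),
    gene_log_hr = gene_log_hr,
    planted_pairs = planted_pairs, pair_log_hr = pair_log_hr,
    baseline_hazard = baseline_hazard,
    censor_rate_target = censor_rate_target,
    batch_shift_sd = batch_shift_sd, batch_scale_sd = batch_scale_sd,
    noise_sd = noise_sd, regimen_mix = regimen_mix,
    id_prefix = id_prefix, seed = as.integer(seed)), class = "sim_config")
}

## Solve the uniform-censoring cap c so that the mean over subjects of
## P(C < T_j) = (1 - exp(-h_j c)) / (h_j c) hits the target fraction.
censor_cap <- function(hazard, target) {
  if (target <= 0) return(Inf)
  f <- function(cc) mean((1 - exp(-hazard * cc)) / (hazard * cc)) - target
  lo <- 1e-8; hi <- 1
  while (f(hi) > 0 && hi < 1e12) hi <- hi * 2
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Simulate a multi-batch expression cohort with survival outcomes
#'
#' See [sim_config()] for the generative model. The emitted expression
#' carries the batch effects; the planted hazard acts on the batch-free
#' expression, so downstream batch adjustment is exercised meaningfully.
#'
#' @param config a [sim_config()] object.
#' @return list with components
#'   \describe{
#'     \item{expression}{list of gene x sample matrices, one per batch.}
#'     \item{clinical}{data.frame with `sample_id`, `os_time`, `os_event`,
#'       `regimen`, `ipi_group`, `coo`, `myc`.}
#'     \item{truth}{ground truth: `planted_fpg_ids`, `planted_upg_ids`,
#'       `planted_pair_ids` (data.frame `upg`, `fpg`), `linear_predictor`
#'       (named per-sample vector), `censor_cap`.}
#'   }
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_genes
  nb <- config$n_samples_per_batch
  n <- sum(nb)
  gene_ids <- sprintf("g%04d", seq_len(G))
  sample_ids <- sprintf("%s%04d", config$id_prefix, seq_len(n))
  batch <- rep(paste0("b", seq_along(nb)), nb)

  ## Planted classes occupy fixed leading indices so that independently
  ## seeded cohorts plant the SAME gene ids — the situation the
  ## cross-cohort intersection is meant to exploit.
  fpg_idx <- seq_len(config$n_fpg_planted)
  upg_idx <- config$n_fpg_planted + seq_len(config$n_upg_planted)

  mu <- stats::rnorm(G, 6, 2)
  eps <- matrix(stats::rnorm(G * n, 0, config$noise_sd), G, n)
  bio <- mu + eps                       # batch-free expression
  dimnames(bio) <- list(gene_ids, sample_ids)

  ## Linear predictor: median-split indicators of planted genes ...
  lp <- numeric(n)
  beta <- numeric(0)
  for (i in upg_idx) lp <- lp + config$gene_log_hr * (bio[i, ] > stats::median(bio[i, ]))
  for (i in fpg_idx) lp <- lp - config$gene_log_hr * (bio[i, ] > stats::median(bio[i, ]))
  ## ... plus binary order indicators of planted pairs on the
  ## quantile-transformed batch-free expression.
  pair_df <- NULL
  if (!is.null(config$planted_pairs) && nrow(config$planted_pairs) > 0) {
    pp <- config$planted_pairs
    pair_genes <- unique(c(upg_idx[pp[, 1]], fpg_idx[pp[, 2]]))
    q <- quantile_uniform(bio[pair_genes, , drop = FALSE])
    for (r in seq_len(nrow(pp))) {
      s <- as.numeric(q[gene_ids[upg_idx[pp[r, 1]]], ] >= q[gene_ids[fpg_idx[pp[r, 2]]], ])
      lp <- lp + config$pair_log_hr * s
    }
    pair_df <- data.frame(upg = gene_ids[upg_idx[pp[, 1]]],
                          fpg = gene_ids[fpg_idx[pp[, 2]]])
  }
  lp <- as.numeric(lp)
  names(lp) <- sample_ids

  hazard <- config$baseline_hazard * exp(lp)
  t_event <- stats::rexp(n, hazard)
  cap <- censor_cap(hazard, config$censor_rate_target)
  if (is.finite(cap)) {
    t_cens <- stats::runif(n, 0, cap)
    os_time <- pmin(t_event, t_cens)
    os_event <- as.integer(t_event <= t_cens)
  } else {
    os_time <- t_event
    os_event <- rep(1L, n)
  }

  regimen <- sample(names(config$regimen_mix), n, replace = TRUE,
                    prob = config$regimen_mix)
  ipi <- sample(c("low", "intermediate", "high"), n, replace = TRUE,
                prob = c(0.35, 0.40, 0.25))
  coo <- sample(c("GCB", "ABC", "UNC", "MHG"), n, replace = TRUE,
                prob = c(0.45, 0.35, 0.15, 0.05))
  myc <- sample(c("normal", "double-hit"), n, replace = TRUE,
                prob = c(0.92, 0.08))

  expr <- vector("list", length(nb))
  names(expr) <- unique(batch)
  col0 <- 0L
  for (b in seq_along(nb)) {
    gamma <- stats::rnorm(G, 0, config$batch_shift_sd)
    delta <- exp(stats::rnorm(G, 0, config$batch_scale_sd))
    j <- col0 + seq_len(nb[b])
    expr[[b]] <- mu + gamma + delta * eps[, j, drop = FALSE]
    dimnames(expr[[b]]) <- list(gene_ids, sample_ids[j])
    col0 <- col0 + nb[b]
  }

  list(expression = expr,
       clinical = data.frame(sample_id = sample_ids, os_time = os_time,
                             os_event = os_event, regimen = regimen,
                             ipi_group = ipi, coo = coo, myc = myc,
                             stringsAsFactors = FALSE),
       truth = list(planted_fpg_ids = gene_ids[fpg_idx],
                    planted_upg_ids = gene_ids[upg_idx],
                    planted_pair_ids = pair_df,
                    linear_predictor = lp,
                    censor_cap = cap))
}

#' Simulate a cell-line drug panel tied to a gene-pair signature
#'
#' Generates per-line expression over the signature's genes so that the
#' intended risk scores sweep the full `0..k` range, then draws log-IC50
#' responses: "responsive" drugs are shifted upward (more resistant) by
#' `effect` in the intended high-risk group, "neutral" drugs are not.
#'
#' @param signature a [pair_signature()].
#' @param n_lines number of cell lines (>= 4).
#' @param n_drugs number of drugs in the panel.
#' @param frac_responsive fraction of drugs carrying the shift.
#' @param effect log-IC50 shift in the high-risk group for responsive drugs.
#' @param noise_sd SD of the response noise (0 gives exact shifts).
#' @param high_risk_min_score score threshold defining the intended
#'   high-risk group (default 3, the `<3` vs `>=3` split).
#' @param seed integer seed.
#' @return list with `expression` (gene x line matrix), `responses`
#'   (line x drug log-IC50 matrix), `truth` (data.frame `drug`, `effect`)
#'   and `target_scores` (the intended per-line risk scores).
#' @export
simulate_drug_panel <- function(signature, n_lines = 17L, n_drugs = 20L,
                                frac_responsive = 0.5, effect = 2,
                                noise_sd = 1, high_risk_min_score = 3L,
                                seed = 1L) {
  stopifnot(inherits(signature, "pair_signature"))
  if (n_lines < 4L) stop("need at least four cell lines", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  set.seed(seed)
  k <- nrow(signature)
  lines <- sprintf("CL%02d", seq_len(n_lines))
  target <- rep(0:k, length.out = n_lines)
  r <- (target + 0.5) / (k + 1)
  ## Pair p switches on at latent-risk threshold p/(k+1): its UPG tracks the
  ## indicator, its FPG the complement, so the order comparison of the
  ## within-panel quantile ranks reproduces the intended indicator.
  genes <- unique(c(signature$upg, signature$fpg))
  expr <- matrix(0, length(genes), n_lines, dimnames = list(genes, lines))
  uses <- lapply(genes, function(g) {
    rbind(if (any(signature$upg == g)) cbind(role = 1, p = which(signature$upg == g)),
          if (any(signature$fpg == g)) cbind(role = 0, p = which(signature$fpg == g)))
  })
  ## Exact tied blocks (no within-block jitter): after the per-gene quantile
  ## transform, a pair's "UPG at or above FPG" comparison then reproduces the
  ## intended indicator for every group size. Exact for signatures whose
  ## genes appear in a single pair; approximate when genes are shared.
  for (i in seq_along(genes)) {
    u <- uses[[i]]
    ind <- sapply(seq_len(nrow(u)), function(rr) {
      tau <- u[rr, "p"] / (k + 1)
      if (u[rr, "role"] == 1) as.numeric(r >= tau) else as.numeric(r < tau)
    })
    expr[i, ] <- rowMeans(matrix(ind, ncol = nrow(u)))
  }
  n_resp <- round(frac_responsive * n_drugs)
  drug_effect <- c(rep(effect, n_resp), rep(0, n_drugs - n_resp))
  drugs <- sprintf("drug%02d", seq_len(n_drugs))
  high <- as.numeric(target >= high_risk_min_score)
  base <- stats::rnorm(n_drugs, 0, 2)
  responses <- outer(rep(1, n_lines), base) + outer(high, drug_effect) +
    matrix(stats::rnorm(n_lines * n_drugs, 0, noise_sd), n_lines, n_drugs)
  dimnames(responses) <- list(lines, drugs)
  list(expression = expr, responses = responses,
       truth = data.frame(drug = drugs, effect = drug_effect,
                          stringsAsFactors = FALSE),
       target_scores = target)
}
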