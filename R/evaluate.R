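## Survival evaluation of a risk score: KM by score level, stratified
## low/high analyses, time-dependent AUC at fixed horizons, linear
## coefficient signatures for comparison, and ranked-AUC summary tables.

join_scores <- function(scores, clinical) {
  m <- merge(clinical, as.data.frame(scores)[, c("sample_id", "score", "group")],
             by = "sample_id")
  if (nrow(m) == 0L)
    stop("no samples shared between scores and clinical table", call. = FALSE)
  m
}

#' Kaplan-Meier curves by risk-score level
#'
#' One KM curve per distinct risk-score value plus a multi-group log-rank
#' test (`k - 1` df for `k` occupied levels).
#'
#' @param scores a `risk_scores` object from [score_samples()].
#' @param clinical clinical table with `sample_id`, `os_time`, `os_event`.
#' @return list with `curves` (named list of `km_curve`, one per occupied
#'   score level), `chi2`, `df`, `p`.
#' @export
km_by_risk <- function(scores, clinical) {
  m <- join_scores(scores, clinical)
  lev <- sort(unique(m$score))
  if (length(lev) < 2L)
    stop("only one occupied risk level: nothing to compare", call. = FALSE)
  curves <- lapply(lev, function(l)
    km_estimate(m$os_time[m$score == l], m$os_event[m$score == l]))
  names(curves) <- paste0("score_", lev)
  lr <- logrank_test(m$os_time, m$os_event, factor(m$score))
  c(list(curves = curves), lr)
}

#' Low/high risk evaluation within clinical strata
#'
#' Within each level of a stratifying clinical field (`ipi_group`, `coo` or
#' `myc`), compares the low- and high-risk groups by KM curves and a
#' log-rank test. Strata that do not contain both risk groups are reported
#' as not evaluable rather than failing.
#'
#' @param scores a `risk_scores` object.
#' @param clinical clinical table containing `stratum_field`.
#' @param stratum_field name of the stratifying column.
#' @return Named list (one entry per stratum level) of lists with
#'   `evaluable`, `n`, and when evaluable `curves` (low/high `km_curve`s),
#'   `chi2`, `df`, `p`.
#' @export
stratified_eval <- function(scores, clinical, stratum_field) {
  if (!stratum_field %in% names(clinical))
    stop("unknown stratum field: ", stratum_field, call. = FALSE)
  m <- join_scores(scores, clinical)
  m <- m[!is.na(m[[stratum_field]]), , drop = FALSE]
  out <- list()
  for (s in unique(m[[stratum_field]])) {
    ms <- m[m[[stratum_field]] == s, , drop = FALSE]
    if (length(unique(ms$group)) < 2L) {
      out[[s]] <- list(evaluable = FALSE, n = nrow(ms))
      next
    }
    lr <- logrank_test(ms$os_time, ms$os_event, ms$group)
    curves <- lapply(split(ms, ms$group), function(d)
      km_estimate(d$os_time, d$os_event))
    out[[s]] <- c(list(evaluable = TRUE, n = nrow(ms), curves = curves), lr)
  }
  out
}

#' Linear coefficient-signature score
#'
#' Per-sample weighted sum `sum(coefficient * expression)` over the
#' signature genes present in the matrix; missing genes are dropped and the
#' coverage fraction reported in a message. This is the conventional scoring
#' rule of published coefficient-based prognostic signatures, used here as
#' the comparator family for the gene-pair score.
#'
#' @param sig data.frame with columns `gene` and `coefficient` (no
#'   duplicate genes); an optional `name` attribute labels messages.
#' @param expr gene x sample expression matrix.
#' @return Named numeric vector of per-sample scores.
#' @export
linear_score <- function(sig, expr) {
  stopifnot(all(c("gene", "coefficient") %in% names(sig)))
  if (anyDuplicated(sig$gene)) stop("duplicate genes in signature", call. = FALSE)
  present <- sig$gene %in% rownames(expr)
  if (!any(present))
    stop("none of the signature genes is measured", call. = FALSE)
  if (!all(present))
    message(sprintf("signature%s: %d/%d genes measured (coverage %.2f)",
                    if (!is.null(attr(sig, "name"))) paste0(" '", attr(sig, "name"), "'") else "",
                    sum(present), length(present), mean(present)))
  s <- sig[present, , drop = FALSE]
  drop(s$coefficient %*% expr[s$gene, , drop = FALSE])
}

#' Mean time-dependent AUC of a marker over several horizons
#'
#' [td_roc()] at each horizon; the summary is the arithmetic mean of the
#' per-horizon AUCs. Horizons that are degenerate in this cohort (no cases
#' or no controls) are excluded from the mean with a warning.
#'
#' @param marker per-sample risk marker, aligned with `clinical` rows.
#' @param clinical clinical table with `os_time`, `os_event`.
#' @param horizons evaluation times.
#' @return list with `auc` (named per-horizon vector, NA when degenerate)
#'   and `mean_auc`.
#' @export
signature_auc <- function(marker, clinical, horizons = c(1, 2, 3)) {
  auc <- vapply(horizons, function(h) {
    tryCatch(td_roc(marker, clinical$os_time, clinical$os_event, h)$auc,
             error = function(e) {
               warning("horizon ", h, " excluded: ", conditionMessage(e),
                       call. = FALSE)
               NA_real_
             })
  }, numeric(1))
  names(auc) <- paste0("t", horizons)
  list(auc = auc, mean_auc = mean(auc, na.rm = TRUE))
}

#' Summarize a per-dataset rank table
#'
#' Given integer ranks of each signature within each dataset (1 = best),
#' returns each signature's mean rank, rounded to two decimals.
#'
#' @param ranks signatures x datasets numeric matrix of within-dataset
#'   ranks; no missing cells.
#' @return Named numeric vector of mean ranks.
#' @export
summarize_rank_table <- function(ranks) {
  ranks <- as.matrix(ranks)
  if (any(is.na(ranks))) stop("rank table has missing cells", call. = FALSE)
  round(rowMeans(ranks), 2)
}

#' Rank signatures by mean AUC across datasets
#'
#' Within each dataset, rank 1 goes to the signature with the highest mean
#' AUC; ties share the minimum rank. The cross-dataset summary is each
#' signature's mean rank (two decimals).
#'
#' @param auc signatures x datasets matrix of mean AUCs; no missing cells.
#' @return An object of class `auc_rank_table`: list with `auc`, `ranks`
#'   (same shape) and `mean_rank` (named, sorted best first).
#' @export
rank_signatures <- function(auc) {
  auc <- as.matrix(auc)
  if (any(is.na(auc))) stop("AUC table has missing cells", call. = FALSE)
  ranks <- apply(auc, 2, function(col) rank(-col, ties.method = "min"))
  dimnames(ranks) <- dimnames(auc)
  mr <- summarize_rank_table(ranks)
  structure(list(auc = auc, ranks = ranks, mean_rank = sort(mr)),
            class = "auc_rank_table")
}

#' @export
print.auc_rank_table <- function(x, ...) {
  cat("Ranked AUC across", ncol(x$ranks), "datasets (1 = best):\n")
  print(data.frame(mean_rank = x$mean_rank))
  invisible(x)
}
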