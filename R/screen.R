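## Prognostic-gene screening: regimen filter, median dichotomization, and the
## per-gene Cox / log-rank / Gehan-Wilcoxon gate, intersected across cohorts.

#' Screening configuration
#'
#' Thresholds and horizons shared by the screening and evaluation stages.
#'
#' @param p_threshold two-sided p-value gate applied to BOTH the log-rank and
#'   the Gehan-Wilcoxon test in the gene screen (default 0.01). The Wald p of
#'   the Cox fit is recorded but not gated on.
#' @param pair_hr_threshold hazard-ratio gate for the pair screen
#'   (default 1.8; a pair is selected when its indicator's HR exceeds it).
#' @param high_risk_min_score risk score at or above which a sample is
#'   called high risk when all signature pairs are measured (default 3,
#'   i.e. the `<3` vs `>=3` split for a 4-pair score); rescaled as
#'   `ceiling(high_risk_min_score * k_available / k)` when only
#'   `k_available` of `k` pairs are measurable.
#' @param eval_horizons follow-up horizons (in `time_unit`) for
#'   time-dependent AUC evaluation.
#' @param keep_regimens regimens defining the training population.
#' @param time_unit unit of the survival times.
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(p_threshold = 0.01, pair_hr_threshold = 1.8,
                          high_risk_min_score = 3L,
                          eval_horizons = c(1, 2, 3),
                          keep_regimens = c("CHOP", "R-CHOP"),
                          time_unit = c("years", "months", "days")) {
  if (p_threshold <= 0 || p_threshold >= 1)
    stop("'p_threshold' must lie in (0, 1)", call. = FALSE)
  if (pair_hr_threshold <= 1)
    stop("'pair_hr_threshold' must exceed 1", call. = FALSE)
  structure(list(p_threshold = p_threshold,
                 pair_hr_threshold = pair_hr_threshold,
                 high_risk_min_score = as.integer(high_risk_min_score),
                 eval_horizons = eval_horizons,
                 keep_regimens = keep_regimens,
                 time_unit = match.arg(time_unit)), class = "screen_config")
}

#' Partition a clinical table by treatment regimen
#'
#' Splits a cohort into the training population (regimens in `keep`) and the
#' remainder, which serves as internal test data.
#'
#' @param clinical clinical data.frame with a `regimen` column.
#' @param keep regimens to keep (non-empty).
#' @return list with `kept` and `internal_test` data.frames
#'   (their union is the input).
#' @export
filter_regimen <- function(clinical, keep = c("CHOP", "R-CHOP")) {
  if (!"regimen" %in% names(clinical))
    stop("clinical table has no 'regimen' column", call. = FALSE)
  if (length(keep) == 0L)
    stop("'keep' must name at least one regimen", call. = FALSE)
  sel <- clinical$regimen %in% keep
  if (!any(sel))
    stop("no samples left after the regimen filter", call. = FALSE)
  list(kept = clinical[sel, , drop = FALSE],
       internal_test = clinical[!sel, , drop = FALSE])
}

#' Median dichotomization
#'
#' 1 for values strictly greater than the sample median ("high" group), 0
#' otherwise; values tied with the median go to the low group, which makes
#' the split deterministic. Depends only on ranks, so any strictly monotone
#' transform of the values yields the identical split.
#'
#' @param values numeric vector, length >= 4.
#' @return Integer 0/1 vector.
#' @export
median_split <- function(values) {
  if (length(values) < 4L) stop("need at least four values to split", call. = FALSE)
  if (length(unique(values)) == 1L)
    stop("constant vector: no median split exists", call. = FALSE)
  as.integer(values > stats::median(values))
}

#' Screen genes for prognostic value
#'
#' Per gene: median dichotomization of its expression, then a univariable
#' Cox fit (hazard ratio of high vs low), a log-rank test and a
#' Gehan-Wilcoxon test. A gene is classified `FPG` (favorable) when its
#' HR < 1 and both test p-values fall below `config$p_threshold`, `UPG`
#' (unfavorable) when HR > 1 with the same gates, and `none` otherwise.
#' No multiple-testing correction is applied at this stage by design; the
#' false positives it admits are controlled downstream by the cross-cohort
#' intersection.
#'
#' @param expr gene x sample expression matrix (already batch-adjusted when
#'   the cohort merges several batches).
#' @param clinical clinical table (already regimen-filtered); every
#'   `sample_id` must be a column of `expr`.
#' @param config a [screen_config()].
#' @return data.frame with one row per gene: `gene_id`, `hr`, `p_wald`,
#'   `p_logrank`, `p_wilcoxon`, `class`, `reason`.
#' @export
screen_genes <- function(expr, clinical, config = screen_config()) {
  missing_s <- setdiff(clinical$sample_id, colnames(expr))
  if (length(missing_s) > 0L)
    stop("samples absent from the expression matrix: ",
         paste(utils::head(missing_s, 5), collapse = ", "),
         if (length(missing_s) > 5) ", ...", call. = FALSE)
  x <- expr[, clinical$sample_id, drop = FALSE]
  time <- clinical$os_time
  event <- clinical$os_event
  out <- data.frame(gene_id = rownames(x), hr = NA_real_, p_wald = NA_real_,
                    p_logrank = NA_real_, p_wilcoxon = NA_real_,
                    class = "none", reason = "", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(x))) {
    split <- tryCatch(median_split(x[i, ]), error = function(e) NULL)
    if (is.null(split) || length(unique(split)) < 2L) {
      out$reason[i] <- "degenerate median split"
      next
    }
    fit <- cox_binary(time, event, split)
    lr <- logrank_test(time, event, split)
    gw <- gehan_wilcoxon_test(time, event, split)
    out$hr[i] <- fit$hr
    out$p_wald[i] <- fit$p_wald
    out$p_logrank[i] <- lr$p
    out$p_wilcoxon[i] <- gw$p
    if (lr$p < config$p_threshold && gw$p < config$p_threshold) {
      if (fit$hr < 1) out$class[i] <- "FPG"
      else if (fit$hr > 1) out$class[i] <- "UPG"
    }
  }
  out
}

#' Intersect screened gene classes across two cohorts
#'
#' Keeps only genes assigned the SAME class in both screens; genes
#' classified FPG in one cohort and UPG in the other are excluded from both
#' outputs.
#'
#' @param a,b results of [screen_genes()] on two cohorts over a shared gene
#'   universe.
#' @return list with `fpg_ids` and `upg_ids` (sorted character vectors).
#' @export
intersect_gene_sets <- function(a, b) {
  pick <- function(res, cls) res$gene_id[res$class == cls]
  list(fpg_ids = sort(intersect(pick(a, "FPG"), pick(b, "FPG"))),
       upg_ids = sort(intersect(pick(a, "UPG"), pick(b, "UPG"))))
}
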