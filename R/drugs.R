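## Drug-sensitivity stratification: score a cell-line panel with a gene-pair
## signature, split at the risk-score threshold, and compare per-drug
## log-IC50 between the low- and high-risk groups.

#' Stratify a cell-line panel by gene-pair risk score
#'
#' Scores the cell lines' expression with [score_samples()] and attaches
#' their drug responses; lines are split into low (`score < threshold`) and
#' high (`score >= threshold`) risk groups.
#'
#' @param expr gene x cell-line expression matrix.
#' @param signature a [pair_signature()].
#' @param responses drug responses: either a cell-line x drug numeric matrix
#'   of log-IC50 values, or a long data.frame with columns `cell_line`,
#'   `drug`, `ln_ic50`.
#' @param config a [screen_config()].
#' @return An object of class `drug_panel`: list with `ln_ic50` (line x drug
#'   matrix over the shared cell lines) and `risk` (the `risk_scores`
#'   data.frame for those lines).
#' @export
stratify_panel <- function(expr, signature, responses, config = screen_config()) {
  if (is.data.frame(responses)) {
    stopifnot(all(c("cell_line", "drug", "ln_ic50") %in% names(responses)))
    lines <- sort(unique(responses$cell_line))
    drugs <- sort(unique(responses$drug))
    wide <- matrix(NA_real_, length(lines), length(drugs),
                   dimnames = list(lines, drugs))
    wide[cbind(match(responses$cell_line, lines),
               match(responses$drug, drugs))] <- responses$ln_ic50
    responses <- wide
  }
  shared <- intersect(colnames(expr), rownames(responses))
  if (length(shared) == 0L)
    stop("no cell lines shared between expression and responses", call. = FALSE)
  risk <- score_samples(signature, expr[, shared, drop = FALSE], config)
  if (length(unique(risk$group)) < 2L)
    stop("all cell lines fall in the '", unique(risk$group),
         "' risk group; consider another score threshold", call. = FALSE)
  structure(list(ln_ic50 = responses[shared, , drop = FALSE], risk = risk),
            class = "drug_panel")
}

#' Compare drug sensitivity between risk groups
#'
#' Per drug, a Welch t-test of log-IC50 between the low- and high-risk cell
#' lines (missing values dropped per drug); drugs are reported in ascending
#' p order. `resistant_in_high` flags drugs whose high-risk mean log-IC50
#' exceeds the low-risk mean. Raw p-values are reported by default,
#' matching the convention of exploratory panel screens; set
#' `p_adjust = "BH"` for Benjamini-Hochberg corrected values in an extra
#' column.
#'
#' @param panel a `drug_panel` from [stratify_panel()].
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return data.frame: `drug`, `n_low`, `n_high`, `mean_low`, `mean_high`,
#'   `resistant_in_high`, `p` (NA when a group has fewer than two values),
#'   and `p_bh` when requested.
#' @export
compare_drugs <- function(panel, p_adjust = c("none", "BH")) {
  stopifnot(inherits(panel, "drug_panel"))
  p_adjust <- match.arg(p_adjust)
  grp <- panel$risk$group[match(rownames(panel$ln_ic50), panel$risk$sample_id)]
  res <- lapply(colnames(panel$ln_ic50), function(d) {
    v <- panel$ln_ic50[, d]
    lo <- v[grp == "low" & !is.na(v)]
    hi <- v[grp == "high" & !is.na(v)]
    if (length(lo) < 2L || length(hi) < 2L)
      return(data.frame(drug = d, n_low = length(lo), n_high = length(hi),
                        mean_low = mean(lo), mean_high = mean(hi),
                        resistant_in_high = NA, p = NA_real_))
    wt <- welch_t(hi, lo)
    data.frame(drug = d, n_low = length(lo), n_high = length(hi),
               mean_low = wt$mean_y, mean_high = wt$mean_x,
               resistant_in_high = wt$mean_x > wt$mean_y, p = wt$p)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$p, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  if (p_adjust == "BH") out$p_bh <- stats::p.adjust(out$p, "BH")
  out
}
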