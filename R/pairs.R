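## The gene-pair scoring core: quantile transformation to within-cohort
## percentile ranks, binary order indicators for (unfavorable, favorable)
## gene pairs, Cox screening of the indicators, cross-cohort intersection,
## and the integer risk score.

#' Quantile transformation to uniform percentile ranks
#'
#' Per gene (independently), values are mapped to their empirical quantiles
#' in `[0, 1]`: `(rank - 1) / (n - 1)` with ties sharing the mean of their
#' rank positions. A constant gene maps every sample to 0.5 (reported in a
#' message). Output preserves gene and sample identity. The transform
#' depends only on ranks, so any strictly monotone per-gene transform of the
#' input yields the identical output.
#'
#' @param expr gene x sample numeric matrix with >= 2 samples.
#' @return Matrix of the same shape with values in `[0, 1]`.
#' @export
quantile_uniform <- function(expr) {
  if (!is.matrix(expr) || ncol(expr) < 2L)
    stop("'expr' must be a matrix with at least two samples", call. = FALSE)
  n <- ncol(expr)
  const <- apply(expr, 1, function(v) length(unique(v)) == 1L)
  if (any(const))
    message(sum(const), " constant gene(s) mapped to 0.5 everywhere")
  out <- t(apply(expr, 1, function(v) (rank(v, ties.method = "average") - 1) / (n - 1)))
  dimnames(out) <- dimnames(expr)
  out
}

#' Enumerate candidate gene pairs
#'
#' Full Cartesian product of the unfavorable and favorable gene sets, in
#' deterministic order (UPG lexicographic, then FPG).
#'
#' @param fpg_ids,upg_ids disjoint non-empty character vectors of gene ids.
#' @return data.frame with columns `upg`, `fpg` (one row per pair).
#' @export
enumerate_pairs <- function(fpg_ids, upg_ids) {
  if (length(fpg_ids) == 0L || length(upg_ids) == 0L)
    stop("both gene sets must be non-empty", call. = FALSE)
  shared <- intersect(fpg_ids, upg_ids)
  if (length(shared) > 0L)
    stop("gene sets overlap: ", paste(utils::head(shared, 5), collapse = ", "),
         call. = FALSE)
  grid <- expand.grid(fpg = sort(fpg_ids), upg = sort(upg_ids),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(upg = grid$upg, fpg = grid$fpg, stringsAsFactors = FALSE)
}

#' Binary order indicator of a gene pair
#'
#' Per sample, 1 when the unfavorable gene's (quantile-transformed)
#' expression is greater than or equal to the favorable gene's, else 0.
#' Exact ties score 1.
#'
#' @param upg,fpg gene ids, both present in `qexpr`.
#' @param qexpr quantile-transformed expression matrix
#'   (see [quantile_uniform()]).
#' @return Integer 0/1 vector named by sample.
#' @export
pair_binary <- function(upg, fpg, qexpr) {
  miss <- setdiff(c(upg, fpg), rownames(qexpr))
  if (length(miss) > 0L)
    stop("gene(s) not in the matrix: ", paste(miss, collapse = ", "),
         "; score with score_samples() to apply the missing-gene policy",
         call. = FALSE)
  stats::setNames(as.integer(qexpr[upg, ] >= qexpr[fpg, ]), colnames(qexpr))
}

#' Screen gene-pair indicators by Cox hazard ratio
#'
#' Per candidate pair, a univariable Cox fit of survival on the binary order
#' indicator; a pair is selected when its HR exceeds
#' `config$pair_hr_threshold`. Pairs whose indicator is constant in the
#' cohort cannot be fit and are skipped with a reason.
#'
#' @param pairs data.frame of candidate pairs from [enumerate_pairs()].
#' @param qexpr quantile-transformed expression of the (regimen-filtered)
#'   cohort.
#' @param clinical clinical table aligned with `qexpr` columns.
#' @param config a [screen_config()].
#' @return data.frame `upg`, `fpg`, `hr`, `p_wald`, `selected`, `reason`.
#' @export
screen_pairs <- function(pairs, qexpr, clinical, config = screen_config()) {
  missing_s <- setdiff(clinical$sample_id, colnames(qexpr))
  if (length(missing_s) > 0L)
    stop("samples absent from the expression matrix: ",
         paste(utils::head(missing_s, 5), collapse = ", "), call. = FALSE)
  x <- qexpr[, clinical$sample_id, drop = FALSE]
  out <- data.frame(pairs, hr = NA_real_, p_wald = NA_real_,
                    selected = FALSE, reason = "", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pairs))) {
    s <- as.integer(x[pairs$upg[i], ] >= x[pairs$fpg[i], ])
    if (length(unique(s)) < 2L) {
      out$reason[i] <- "constant indicator"
      next
    }
    fit <- cox_binary(clinical$os_time, clinical$os_event, s)
    out$hr[i] <- fit$hr
    out$p_wald[i] <- fit$p_wald
    out$selected[i] <- fit$hr > config$pair_hr_threshold
  }
  out
}

#' Construct a gene-pair signature
#'
#' @param upg,fpg equal-length character vectors of gene ids; row i is the
#'   ordered pair (unfavorable gene, favorable gene).
#' @param name signature name.
#' @param provenance free-text provenance note.
#' @return data.frame of class `pair_signature` with columns `upg`, `fpg`,
#'   sorted lexicographically; duplicate pairs are an error.
#' @export
pair_signature <- function(upg, fpg, name = "pair signature",
                           provenance = "") {
  stopifnot(length(upg) == length(fpg))
  if (any(upg == fpg)) stop("a pair cannot use one gene twice", call. = FALSE)
  df <- data.frame(upg = as.character(upg), fpg = as.character(fpg),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df)) stop("duplicate pairs in signature", call. = FALSE)
  df <- df[order(df$upg, df$fpg), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("pair_signature", "data.frame"),
            name = name, provenance = provenance)
}

#' @export
print.pair_signature <- function(x, ...) {
  cat(sprintf("Gene-pair signature '%s': %d pair(s), %d unique gene(s)\n",
              attr(x, "name"), nrow(x), length(unique(c(x$upg, x$fpg)))))
  print.data.frame(x, ...)
  invisible(x)
}

#' Intersect selected pairs across two cohorts
#'
#' The final signature: pairs selected in BOTH cohorts' pair screens. An
#' empty intersection yields an empty signature with a warning (the caller
#' decides how to proceed).
#'
#' @param a,b results of [screen_pairs()] on the two cohorts.
#' @param name name for the resulting signature.
#' @return A [pair_signature()]; its `n_genes` attribute records the
#'   unique-gene count.
#' @export
intersect_pairs <- function(a, b, name = "intersected signature") {
  ka <- a[a$selected, c("upg", "fpg")]
  kb <- b[b$selected, c("upg", "fpg")]
  common <- merge(ka, kb)
  if (nrow(common) == 0L) {
    warning("no pairs selected in both cohorts: empty signature")
    sig <- structure(data.frame(upg = character(0), fpg = character(0)),
                     class = c("pair_signature", "data.frame"),
                     name = name, provenance = "cross-cohort intersection")
  } else {
    sig <- pair_signature(common$upg, common$fpg, name = name,
                          provenance = "cross-cohort intersection")
  }
  attr(sig, "n_genes") <- length(unique(c(sig$upg, sig$fpg)))
  sig
}

#' Risk scores from a gene-pair signature
#'
#' Applies the signature to a (raw, log-scale) expression matrix: the matrix
#' is restricted to the signature genes present, quantile-transformed on
#' this cohort alone, and the risk score of each sample is the plain sum of
#' the binary pair indicators over the pairs whose two genes are both
#' measured (`k_available` of the `k` signature pairs). No coefficients are
#' involved: with all pairs measured the score takes the integer values
#' `0..k`. A sample is called high risk when its score reaches
#' `ceiling(high_risk_min_score * k_available / k)` (which is
#' `high_risk_min_score` itself when everything is measured).
#'
#' @param signature a [pair_signature()].
#' @param expr gene x sample expression matrix.
#' @param config a [screen_config()] (supplies `high_risk_min_score`).
#' @return data.frame of class `risk_scores`: `sample_id`, `score`,
#'   `k_available`, `group` (`"low"`/`"high"`); the applied threshold is in
#'   attribute `"threshold"`.
#' @export
score_samples <- function(signature, expr, config = screen_config()) {
  stopifnot(inherits(signature, "pair_signature"))
  if (nrow(signature) == 0L) stop("empty signature", call. = FALSE)
  genes <- unique(c(signature$upg, signature$fpg))
  present <- intersect(genes, rownames(expr))
  avail <- signature$upg %in% present & signature$fpg %in% present
  if (!any(avail))
    stop("no signature pair has both genes measured in this matrix", call. = FALSE)
  if (!all(avail))
    message(sum(!avail), " pair(s) dropped: member gene(s) not measured")
  q <- quantile_uniform(expr[present, , drop = FALSE])
  k_avail <- sum(avail)
  score <- integer(ncol(expr))
  for (i in which(avail))
    score <- score + as.integer(q[signature$upg[i], ] >= q[signature$fpg[i], ])
  threshold <- as.integer(ceiling(config$high_risk_min_score * k_avail / nrow(signature)))
  structure(
    data.frame(sample_id = colnames(expr), score = score,
               k_available = k_avail,
               group = ifelse(score >= threshold, "high", "low"),
               stringsAsFactors = FALSE),
    class = c("risk_scores", "data.frame"), threshold = threshold)
}
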