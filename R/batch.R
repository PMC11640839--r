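## Cohort integration: merge same-platform expression matrices on their
## common genes, then remove per-batch location/scale effects by parametric
## empirical-Bayes adjustment (ComBat-style location/scale model).

#' Merge expression matrices on their common genes
#'
#' Column-concatenates a list of gene x sample matrices restricted to the
#' intersection of their gene ids, in lexicographic gene order. Each sample
#' is tagged with the batch it came from (the list names, or `batch1`,
#' `batch2`, ... if unnamed) via the `"batch"` attribute of the result.
#'
#' @param matrices list of >= 2 numeric matrices with gene-id rownames and
#'   sample-id colnames.
#' @return A merged numeric matrix with a `"batch"` attribute (character
#'   vector aligned with the columns; retrieve it with [batch_labels()]).
#' @export
merge_common_genes <- function(matrices) {
  if (!is.list(matrices) || length(matrices) < 2L)
    stop("need a list of at least two expression matrices", call. = FALSE)
  labs <- names(matrices)
  if (is.null(labs) || any(labs == ""))
    labs <- paste0("batch", seq_along(matrices))
  genes <- Reduce(intersect, lapply(matrices, rownames))
  if (length(genes) == 0L)
    stop("the matrices share no gene ids; nothing to merge", call. = FALSE)
  genes <- sort(genes)
  samples <- unlist(lapply(matrices, colnames), use.names = FALSE)
  dup <- unique(samples[duplicated(samples)])
  if (length(dup) > 0L)
    stop("duplicate sample ids across sources: ", paste(dup, collapse = ", "),
         call. = FALSE)
  merged <- do.call(cbind, lapply(matrices, function(m) m[genes, , drop = FALSE]))
  attr(merged, "batch") <- rep(labs, vapply(matrices, ncol, integer(1)))
  merged
}

#' Batch labels of a merged expression matrix
#'
#' @param x a matrix produced by [merge_common_genes()] (or any matrix with a
#'   `"batch"` attribute).
#' @return Character vector of per-column batch labels, or `NULL`.
#' @export
batch_labels <- function(x) attr(x, "batch")

#' Empirical-Bayes batch adjustment
#'
#' Parametric location/scale batch correction of a log-scale expression
#' matrix: per gene, the data are standardized by the pooled (batch-effect
#' corrected) mean and variance; per-batch gene means get a normal shrinkage
#' prior and per-batch gene variances an inverse-gamma shrinkage prior, both
#' with hyperparameters estimated across genes by the method of moments; the
#' posterior batch effects are solved by iterating the two conditional modes
#' to convergence and removed before back-transformation.
#'
#' All variances use divide-by-n (maximum-likelihood) denominators, so two
#' identical batches produce a null adjustment exactly. Re-adjusting an
#' already adjusted matrix is a strong contraction (batch means stay put and
#' entries move by a few percent of the first pass at most) but not an exact
#' no-op: an empirical-Bayes variance model keeps shrinking the sampling
#' spread of the within-batch variances slightly on every pass.
#'
#' A gene whose variance is zero within some batch cannot support a scale
#' estimate there; such genes receive the location adjustment only, and are
#' reported in a message.
#'
#' @param x numeric gene x sample matrix (log-scale expression).
#' @param batch per-sample batch labels; defaults to the `"batch"` attribute
#'   set by [merge_common_genes()]. With a single batch the input is returned
#'   unchanged (there is nothing to correct).
#' @param tol,max_iter convergence control for the conditional-mode
#'   iteration of the posterior batch effects.
#' @return The adjusted matrix, same dimensions and dimnames, with the
#'   `"batch"` attribute preserved.
#' @export
combat_adjust <- function(x, batch = batch_labels(x), tol = 1e-6, max_iter = 200L) {
  if (!is.matrix(x) || !is.numeric(x)) stop("'x' must be a numeric matrix", call. = FALSE)
  if (is.null(batch)) stop("no batch labels supplied or attached to 'x'", call. = FALSE)
  if (length(batch) != ncol(x)) stop("'batch' must have one label per sample", call. = FALSE)
  batch <- as.factor(batch)
  if (nlevels(batch) < 2L) return(x)
  nb <- table(batch)
  if (any(nb < 2L))
    stop("every batch needs at least two samples", call. = FALSE)
  n <- ncol(x); G <- nrow(x)
  levs <- levels(batch)
  B <- length(levs)
  idx <- lapply(levs, function(b) which(batch == b))

  ## Per-gene location/scale model: x = alpha + gamma_b + delta_b * eps.
  ## alpha: sample-size weighted mean of the batch means.
  bmean <- vapply(idx, function(j) rowMeans(x[, j, drop = FALSE]), numeric(G))
  bmean <- matrix(bmean, nrow = G)
  alpha <- drop(bmean %*% (as.numeric(nb) / n))
  ## Pooled variance of the location-corrected data (MLE denominator).
  centred <- x - alpha
  for (b in seq_len(B)) centred[, idx[[b]]] <- centred[, idx[[b]]] - (bmean[, b] - alpha)
  var_pooled <- rowSums(centred^2) / n
  zero_pool <- var_pooled <= 0
  if (any(zero_pool)) {
    message(sum(zero_pool), " gene(s) constant across all samples; left unadjusted")
    var_pooled[zero_pool] <- 1   # neutralized below
  }
  sd_pooled <- sqrt(var_pooled)

  z <- (x - alpha) / sd_pooled
  gamma_hat <- vapply(idx, function(j) rowMeans(z[, j, drop = FALSE]), numeric(G))
  gamma_hat <- matrix(gamma_hat, nrow = G)
  delta_hat <- vapply(seq_len(B), function(b) {
    zj <- z[, idx[[b]], drop = FALSE]
    rowSums((zj - gamma_hat[, b])^2) / length(idx[[b]])
  }, numeric(G))
  delta_hat <- matrix(delta_hat, nrow = G)
  zero_scale <- delta_hat <= 0
  n_zero_scale <- sum(apply(zero_scale, 1, any) & !zero_pool)
  if (n_zero_scale > 0)
    message(n_zero_scale,
            " gene(s) with zero variance within a batch; location-only adjustment there")

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (b in seq_len(B)) {
    ok <- !zero_pool & !zero_scale[, b]
    if (sum(ok) < 2L) { delta_star[, b] <- 1; next }
    nbk <- length(idx[[b]])
    g_hat <- gamma_hat[ok, b]; d_hat <- delta_hat[ok, b]
    ## Method-of-moments hyperparameters across genes.
    g_bar <- mean(g_hat); t2 <- stats::var(g_hat)
    m_d <- mean(d_hat); v_d <- stats::var(d_hat)
    ## Inverse-gamma (a_prior, b_prior) matched to mean and variance of d_hat.
    a_prior <- if (v_d > 0) (2 * v_d + m_d^2) / v_d else Inf
    b_prior <- if (v_d > 0) (m_d * v_d + m_d^3) / v_d else NA
    g_star <- g_hat; d_star <- d_hat
    if (t2 > 0 && is.finite(a_prior)) {
      sumsq <- d_hat * nbk + nbk * (g_hat - g_hat)^2  # placeholder, updated in loop
      for (it in seq_len(max_iter)) {
        g_new <- (nbk * t2 * g_hat + d_star * g_bar) / (nbk * t2 + d_star)
        sumsq <- nbk * d_hat + nbk * (g_hat - g_new)^2
        d_new <- (0.5 * sumsq + b_prior) / (nbk / 2 + a_prior - 1)
        delta_change <- max(abs(g_new - g_star) / pmax(abs(g_star), 1),
                            abs(d_new - d_star) / pmax(abs(d_star), 1))
        g_star <- g_new; d_star <- d_new
        if (delta_change < tol) break
      }
    } else if (t2 > 0) {
      ## Degenerate variance prior (all delta_hat equal): shrink means only.
      g_star <- (nbk * t2 * g_hat + d_hat * g_bar) / (nbk * t2 + d_hat)
    }
    ## t2 == 0 (all gamma_hat identical, e.g. identical batches): keep raw
    ## estimates; they are already the common value.
    gamma_star[ok, b] <- g_star
    delta_star[ok, b] <- d_star
    delta_star[!ok, b] <- 1
    gamma_star[zero_pool, b] <- 0
  }
  delta_star[delta_star <= 0] <- 1

  out <- z
  for (b in seq_len(B)) {
    j <- idx[[b]]
    out[, j] <- (z[, j] - gamma_star[, b]) / sqrt(delta_star[, b])
  }
  out <- out * sd_pooled + alpha
  out[zero_pool, ] <- x[zero_pool, ]
  dimnames(out) <- dimnames(x)
  attr(out, "batch") <- attr(x, "batch")
  out
}
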