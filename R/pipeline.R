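## End-to-end workflow: integrate batches per cohort, filter by regimen,
## screen genes, screen pair indicators, intersect across cohorts into the
## final signature, score every cohort and evaluate.

#' Run the full gene-pair signature pipeline
#'
#' Executes, for two (or more) training cohorts:
#' integrate batches (merge on common genes + empirical-Bayes adjustment)
#' -> regimen filter -> per-gene screen -> quantile transform -> pair
#' enumeration and Cox screen -> cross-cohort intersection into the final
#' signature -> risk scoring -> KM-by-risk and time-dependent AUC
#' evaluation. Every intermediate table is written to `out_dir` along with a
#' run log (versions, seed, config echo); a stage failure aborts with the
#' stage name while completed intermediates persist.
#'
#' @param config either a path to a YAML file or a list, with entries:
#'   \describe{
#'     \item{seed}{global seed for the stochastic stages.}
#'     \item{p_threshold, pair_hr_threshold, high_risk_min_score,
#'       horizons, keep_regimens}{optional screening/evaluation settings
#'       (see [screen_config()]).}
#'     \item{simulation}{a list of >= 2 blocks of [sim_config()] arguments
#'       (one per cohort); or}
#'     \item{cohorts}{a list of >= 2 blocks, each with `expression`
#'       (vector of >= 1 matrix paths, one per batch) and `clinical`
#'       (one table path).}
#'   }
#' @param out_dir artifact directory (created if needed).
#' @return (Invisibly) list with per-cohort screens, the signature, scores
#'   and evaluation summaries.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("'config' must be a list or a YAML path", call. = FALSE)
  n_cohorts <- if (!is.null(config$simulation)) length(config$simulation)
               else length(config$cohorts)
  if (is.null(n_cohorts) || n_cohorts < 2L)
    stop("config must name at least two training cohorts ",
         "(simulation blocks or cohort blocks)", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  sc_args <- config[intersect(names(config),
                              c("p_threshold", "pair_hr_threshold",
                                "high_risk_min_score"))]
  if (!is.null(config$horizons)) sc_args$eval_horizons <- config$horizons
  if (!is.null(config$keep_regimens)) sc_args$keep_regimens <- config$keep_regimens
  sconf <- do.call(screen_config, sc_args)

  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("pairRisk %s | R %s | seed %d",
       as.character(utils::packageVersion("pairRisk")),
       paste(R.version$major, R.version$minor, sep = "."), seed)
  logf("config: %s", gsub("\n", " | ", yaml::as.yaml(config)))

  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      logf("FAILED at stage '%s': %s", name, conditionMessage(e))
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  cohorts <- vector("list", n_cohorts)
  for (i in seq_len(n_cohorts)) {
    ci <- stage(paste0("load_cohort_", i), function() {
      if (!is.null(config$simulation)) {
        block <- config$simulation[[i]]
        if (is.null(block$seed)) block$seed <- seed + i
        if (is.null(block$id_prefix)) block$id_prefix <- paste0("C", i, "S")
        sim <- simulate_cohort(do.call(sim_config, block))
        list(expression = sim$expression, clinical = sim$clinical,
             truth = sim$truth)
      } else {
        block <- config$cohorts[[i]]
        mats <- lapply(block$expression, read_expression)
        names(mats) <- paste0("batch", seq_along(mats))
        list(expression = mats, clinical = read_clinical(block$clinical),
             truth = NULL)
      }
    })
    adjusted <- stage(paste0("integrate_cohort_", i), function() {
      if (length(ci$expression) > 1L)
        combat_adjust(merge_common_genes(ci$expression))
      else ci$expression[[1]]
    })
    parts <- stage(paste0("filter_regimen_cohort_", i),
                   function() filter_regimen(ci$clinical, sconf$keep_regimens))
    screen <- stage(paste0("screen_genes_cohort_", i), function() {
      res <- screen_genes(adjusted, parts$kept, sconf)
      write_tsv(res, file.path(out_dir, sprintf("gene_screen_%d.tsv", i)))
      res
    })
    logf("cohort %d: %d samples kept / %d internal test; %d FPG, %d UPG",
         i, nrow(parts$kept), nrow(parts$internal_test),
         sum(screen$class == "FPG"), sum(screen$class == "UPG"))
    cohorts[[i]] <- list(data = ci, adjusted = adjusted, parts = parts,
                         screen = screen)
  }

  sets <- stage("intersect_gene_sets", function() {
    s <- Reduce(function(a, b) {
      list(fpg_ids = intersect(a$fpg_ids, b$fpg_ids),
           upg_ids = intersect(a$upg_ids, b$upg_ids))
    }, lapply(cohorts, function(co)
      intersect_gene_sets(co$screen, co$screen))[-1],
    intersect_gene_sets(cohorts[[1]]$screen, cohorts[[2]]$screen))
    if (length(s$fpg_ids) == 0L || length(s$upg_ids) == 0L)
      stop("no favorable or no unfavorable genes survive the intersection")
    s
  })
  logf("intersected sets: %d FPG, %d UPG", length(sets$fpg_ids),
       length(sets$upg_ids))

  pairs <- stage("enumerate_pairs",
                 function() enumerate_pairs(sets$fpg_ids, sets$upg_ids))
  pair_screens <- lapply(seq_len(n_cohorts), function(i) {
    stage(paste0("screen_pairs_cohort_", i), function() {
      co <- cohorts[[i]]
      kept <- co$parts$kept
      q <- quantile_uniform(co$adjusted[, kept$sample_id, drop = FALSE])
      res <- screen_pairs(pairs, q, kept, sconf)
      write_tsv(res, file.path(out_dir, sprintf("pair_screen_%d.tsv", i)))
      res
    })
  })
  signature <- stage("intersect_pairs", function() {
    sig <- Reduce(function(acc, ps) {
      sel <- ps[ps$selected, c("upg", "fpg")]
      acc[paste(acc$upg, acc$fpg) %in% paste(sel$upg, sel$fpg), , drop = FALSE]
    }, pair_screens[-1],
    pair_screens[[1]][pair_screens[[1]]$selected, c("upg", "fpg")])
    if (nrow(sig) == 0L)
      warning("no pairs selected in every cohort: empty signature")
    sig <- pair_signature(sig$upg, sig$fpg, name = "pipeline signature",
                          provenance = "cross-cohort intersection")
    write_signature_json(sig, file.path(out_dir, "signature.json"))
    sig
  })
  logf("signature: %d pair(s), %d unique gene(s)", nrow(signature),
       length(unique(c(signature$upg, signature$fpg))))

  evaluation <- lapply(seq_len(n_cohorts), function(i) {
    stage(paste0("evaluate_cohort_", i), function() {
      co <- cohorts[[i]]
      scores <- score_samples(signature, co$adjusted, sconf)
      write_tsv(as.data.frame(scores),
                file.path(out_dir, sprintf("scores_%d.tsv", i)))
      kept_scores <- scores[scores$sample_id %in% co$parts$kept$sample_id, ]
      km <- tryCatch(km_by_risk(kept_scores, co$parts$kept),
                     error = function(e) NULL)
      auc <- signature_auc(
        kept_scores$score[match(co$parts$kept$sample_id, kept_scores$sample_id)],
        co$parts$kept, sconf$eval_horizons)
      logf("cohort %d evaluation: logrank p = %s, mean 1-3y AUC = %.3f", i,
           if (is.null(km)) "NA" else format(km$p, digits = 3), auc$mean_auc)
      list(scores = scores, km_by_risk = km, auc = auc)
    })
  })
  summary_df <- data.frame(
    cohort = seq_len(n_cohorts),
    logrank_p = vapply(evaluation, function(e)
      if (is.null(e$km_by_risk)) NA_real_ else e$km_by_risk$p, numeric(1)),
    mean_auc = vapply(evaluation, function(e) e$auc$mean_auc, numeric(1)))
  write_tsv(summary_df, file.path(out_dir, "evaluation.tsv"))
  invisible(list(cohorts = cohorts, gene_sets = sets,
                 pair_screens = pair_screens, signature = signature,
                 evaluation = evaluation, config = config))
}
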