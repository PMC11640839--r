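## Readers and writers for the package's table formats. The canonical
## dialect is TSV (tab-delimited, UTF-8, "." decimal); CSV is accepted on
## read. Numeric output is written with 15 significant digits so a write /
## read round trip reproduces values to ~1e-12.

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty file: ", path, call. = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
}

#' Read a gene x sample expression table
#'
#' First column gene id, header row of sample ids; TSV or CSV. Duplicate
#' gene ids are rejected with their row numbers; non-numeric cells are an
#' error with coordinates; missing cells (`NA` or empty) are imputed by the
#' gene median and counted in a warning.
#'
#' @param path file path.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  df <- read_delim_auto(path)
  if (ncol(df) < 2L) stop("expression table needs gene ids plus >= 1 sample",
                          call. = FALSE)
  genes <- df[[1]]
  dup <- which(duplicated(genes) | duplicated(genes, fromLast = TRUE))
  if (length(dup) > 0L)
    stop("duplicated gene id(s): ",
         paste(unique(genes[dup]), collapse = ", "),
         " (rows ", paste(dup, collapse = ", "), ")", call. = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  vals[vals == "" | vals == "NA"] <- NA
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals),
                                 dimnames = list(genes, colnames(vals))))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-numeric cell(s), e.g. gene ", genes[bad[1, 1]],
         ", sample ", colnames(num)[bad[1, 2]],
         " ('", vals[bad[1, , drop = FALSE]], "')", call. = FALSE)
  n_missing <- sum(is.na(num))
  if (n_missing > 0L) {
    for (i in which(rowSums(is.na(num)) > 0)) {
      med <- stats::median(num[i, ], na.rm = TRUE)
      if (is.na(med))
        stop("gene ", genes[i], " has no observed values", call. = FALSE)
      num[i, is.na(num[i, ])] <- med
    }
    warning(n_missing, " missing value(s) imputed by gene median")
  }
  num
}

clinical_vocab <- list(regimen = c("CHOP", "R-CHOP", "other"),
                       ipi_group = c("low", "intermediate", "high"),
                       coo = c("GCB", "ABC", "UNC", "MHG"),
                       myc = c("normal", "double-hit"))

#' Read a clinical survival table
#'
#' Requires columns `sample_id`, `os_time` (> 0) and `os_event` (0/1);
#' optional categorical columns (`regimen`, `ipi_group`, `coo`, `myc`) are
#' checked against their vocabularies, with missing values allowed.
#'
#' @param path file path (TSV or CSV).
#' @return data.frame.
#' @export
read_clinical <- function(path) {
  df <- read_delim_auto(path)
  need <- c("sample_id", "os_time", "os_event")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  df$os_time <- suppressWarnings(as.numeric(df$os_time))
  bad_t <- which(is.na(df$os_time) | df$os_time <= 0)
  if (length(bad_t) > 0L)
    stop("os_time must be positive (row ", paste(bad_t, collapse = ", "), ")",
         call. = FALSE)
  ev <- suppressWarnings(as.numeric(df$os_event))
  bad_e <- which(!ev %in% c(0, 1))
  if (length(bad_e) > 0L)
    stop("os_event must be 0 or 1 (row ", paste(bad_e, collapse = ", "), ")",
         call. = FALSE)
  df$os_event <- as.integer(ev)
  for (col in intersect(names(clinical_vocab), names(df))) {
    v <- df[[col]]
    v[v == ""] <- NA
    unknown <- setdiff(unique(v[!is.na(v)]), clinical_vocab[[col]])
    if (length(unknown) > 0L)
      stop("unknown ", col, " value(s): ", paste(unknown, collapse = ", "),
           "; expected one of ", paste(clinical_vocab[[col]], collapse = ", "),
           call. = FALSE)
    df[[col]] <- v
  }
  df
}

fmt_num <- function(x) {
  if (is.numeric(x)) sprintf("%.15g", x) else x
}

write_tsv <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt_num), check.names = FALSE,
                       stringsAsFactors = FALSE)
  names(out) <- names(df)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an expression matrix as TSV
#'
#' @param expr gene x sample matrix.
#' @param path output path; first column `gene_id`.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr),
                   as.data.frame(expr, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Write a clinical table as TSV
#' @param clinical data.frame.
#' @param path output path.
#' @export
write_clinical <- function(clinical, path) write_tsv(clinical, path)

#' Write a Kaplan-Meier curve as TSV
#'
#' Columns `time`, `survival`, `at_risk`.
#' @param curve a `km_curve`.
#' @param path output path.
#' @export
write_km_curve <- function(curve, path) {
  stopifnot(inherits(curve, "km_curve"))
  write_tsv(data.frame(time = curve$event_times, survival = curve$survival,
                       at_risk = curve$at_risk), path)
}

#' Write / read a gene-pair signature as JSON
#'
#' The serialized form is
#' `{"name": ..., "provenance": ..., "pairs": [{"upg": id, "fpg": id}, ...]}`.
#'
#' @param signature a [pair_signature()].
#' @param path file path.
#' @return `read_signature_json` returns a [pair_signature()].
#' @export
write_signature_json <- function(signature, path) {
  stopifnot(inherits(signature, "pair_signature"))
  jsonlite::write_json(
    list(name = attr(signature, "name"),
         provenance = attr(signature, "provenance"),
         pairs = data.frame(upg = signature$upg, fpg = signature$fpg)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_signature_json
#' @export
read_signature_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pair_signature(x$pairs$upg, x$pairs$fpg,
                 name = if (!is.null(x$name)) x$name else "signature",
                 provenance = if (!is.null(x$provenance)) x$provenance else "")
}

#' Read coefficient signatures from TSV
#'
#' Long format with columns `signature`, `gene`, `coefficient`; returns one
#' data.frame per signature, ready for [linear_score()].
#'
#' @param path file path.
#' @return Named list of data.frames with columns `gene`, `coefficient`.
#' @export
read_coefficient_signatures <- function(path) {
  df <- read_delim_auto(path)
  need <- c("signature", "gene", "coefficient")
  if (!all(need %in% names(df)))
    stop("expected columns: ", paste(need, collapse = ", "), call. = FALSE)
  df$coefficient <- as.numeric(df$coefficient)
  lapply(split(df[, c("gene", "coefficient")], df$signature), function(d) {
    rownames(d) <- NULL
    d
  })
}
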