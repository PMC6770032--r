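#' Read a feature-by-sample expression matrix
#'
#' Reads a tab-separated expression table (log-scale intensities): first
#' column feature ids, header row sample ids, remaining cells numeric.
#' Row and column order are preserved as on disk.
#'
#' @param path Path to a tab-separated file.
#' @param kind Feature kind, `"mirna"` or `"gene"`; stored as the `kind`
#'   attribute of the returned matrix.
#' @return Numeric matrix (features x samples) with feature ids as rownames,
#'   sample ids as colnames and a `kind` attribute.
#' @export
read_expression <- function(path, kind = c("mirna", "gene")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_usage("expression file not found: %s", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1])[1]
    stop_data("ragged table %s: line %d has %d fields, line 1 has %d",
              path, bad, nf[bad], nf[1])
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          quote = "")
  if (ncol(df) < 2L) stop_data("%s: need a feature-id column plus >= 1 sample column", path)
  feature_ids <- df[[1]]
  sample_ids <- colnames(df)[-1]
  if (anyDuplicated(feature_ids)) {
    dup <- unique(feature_ids[duplicated(feature_ids)])
    stop_data("duplicated feature id(s) in %s: %s", path,
              paste(utils::head(dup, 5), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    dup <- unique(sample_ids[duplicated(sample_ids)])
    stop_data("duplicated sample id(s) in %s: %s", path,
              paste(utils::head(dup, 5), collapse = ", "))
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop_data("non-numeric cell in %s at feature '%s', sample '%s' (value '%s')",
              path, feature_ids[bad[1, 1]], sample_ids[bad[1, 2]],
              vals[bad[1, 1], bad[1, 2]])
  }
  if (!all(is.finite(num))) {
    bad <- which(!is.finite(num), arr.ind = TRUE)
    stop_data("non-finite value in %s at feature '%s', sample '%s'",
              path, feature_ids[bad[1, 1]], sample_ids[bad[1, 2]])
  }
  dimnames(num) <- list(feature_ids, sample_ids)
  attr(num, "kind") <- kind
  num
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]: tab-separated, feature ids in the first
#' column (`feature_id` header), sample ids as the remaining header fields.
#'
#' @param mat Numeric matrix with rownames (features) and colnames (samples).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop_usage("matrix must have feature rownames and sample colnames")
  df <- data.frame(feature_id = rownames(mat), mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Continuous age at diagnosis in years
#'
#' Age is the calendar-day difference between diagnosis and birth divided by
#' the constant 365 (no leap-year correction): computing age from the exact
#' day count makes the covariate continuous, so that rank ties in age are
#' avoided and exact Spearman p-values remain valid.
#'
#' @param birth_date,diagnosis_date Dates (or ISO-8601 strings), vectorized.
#' @return Numeric vector of ages in years (day difference / 365).
#' @examples
#' compute_age_years("2000-01-01", "2010-01-01")  # 3653/365
#' @export
compute_age_years <- function(birth_date, diagnosis_date) {
  b <- as.Date(birth_date)
  d <- as.Date(diagnosis_date)
  if (anyNA(b) || anyNA(d)) stop_data("unparseable date (expected ISO-8601 yyyy-mm-dd)")
  days <- as.numeric(d - b)
  if (any(days < 0)) {
    i <- which(days < 0)[1]
    stop_data("diagnosis date %s precedes birth date %s", d[i], b[i])
  }
  days / 365
}

.tissue_levels <- c("tumor", "normal")
.age_group_levels <- c("PEDS", "AYA")

#' Read per-sample clinical metadata
#'
#' Expects columns `sample_id`, `birth_date`, `diagnosis_date`, `tissue`
#' (values `tumor`/`normal`); optional `age_group` (`PEDS`/`AYA`, otherwise
#' derived from age: PEDS below 15 years). Comma- or tab-separated, sniffed
#' from the header line. Continuous `age_years` is populated with
#' [compute_age_years()]. Tied ages trigger a warning (not an error): exact
#' Spearman p-values downstream assume a tie-free covariate and degrade to
#' approximate p-values when ties are present.
#'
#' @param path Path to the metadata table.
#' @return `data.frame` with one row per sample and an `age_years` column.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop_usage("sample metadata file not found: %s", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          stringsAsFactors = FALSE, colClasses = "character")
  required <- c("sample_id", "birth_date", "diagnosis_date", "tissue")
  missing <- setdiff(required, colnames(df))
  if (length(missing) > 0L)
    stop_data("%s: missing required column(s): %s", path,
              paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop_data("%s: duplicated sample id(s): %s", path,
              paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(df$tissue), .tissue_levels)
  if (length(bad) > 0L)
    stop_data("%s: unknown tissue label '%s'; accepted labels: %s",
              path, bad[1], paste(.tissue_levels, collapse = ", "))
  out <- data.frame(
    sample_id = df$sample_id,
    # strict ISO-8601: a lenient as.Date() would quietly accept e.g. d/m/y
    birth_date = as.Date(df$birth_date, format = "%Y-%m-%d"),
    diagnosis_date = as.Date(df$diagnosis_date, format = "%Y-%m-%d"),
    tissue = df$tissue,
    stringsAsFactors = FALSE
  )
  if (anyNA(out$birth_date) || anyNA(out$diagnosis_date)) {
    i <- which(is.na(out$birth_date) | is.na(out$diagnosis_date))[1]
    stop_data("%s: unparseable date for sample '%s' (expected ISO-8601)",
              path, df$sample_id[i])
  }
  out$age_years <- compute_age_years(out$birth_date, out$diagnosis_date)
  if (any(out$age_years <= 0)) {
    i <- which(out$age_years <= 0)[1]
    stop_data("%s: non-positive age for sample '%s'", path, out$sample_id[i])
  }
  if ("age_group" %in% colnames(df)) {
    bad <- setdiff(unique(df$age_group), .age_group_levels)
    if (length(bad) > 0L)
      stop_data("%s: unknown age_group label '%s'; accepted: %s",
                path, bad[1], paste(.age_group_levels, collapse = ", "))
    out$age_group <- df$age_group
  } else {
    out$age_group <- ifelse(out$age_years < 15, "PEDS", "AYA")
  }
  if (anyDuplicated(out$age_years)) {
    warning(sprintf(
      "%s: %d sample(s) share identical age_years; tied ages invalidate exact Spearman p-values (approximate p-values will be used)",
      path, sum(duplicated(out$age_years))))
  }
  out
}

#' Write per-sample metadata
#'
#' @param samples Data frame as returned by [read_samples()] or
#'   [simulate_cohort()].
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  cols <- intersect(c("sample_id", "birth_date", "diagnosis_date",
                      "tissue", "age_group"), colnames(samples))
  utils::write.table(samples[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a miRNA-to-gene target table
#'
#' Reads a two-column pair table (miRNA id, target gene id), emulating an
#' export from a target-interaction aggregator. Duplicate pairs are stored
#' once; pairs whose gene is absent from `gene_universe` (the expression
#' matrix's features) are dropped and the count of dropped pairs reported
#' via a message.
#'
#' @param path Path to a two-column tab-separated pair file with a header.
#' @param gene_universe Character vector of gene ids present in the gene
#'   expression matrix; pairs outside it are dropped. `NULL` keeps all pairs.
#' @return `data.frame` with columns `mirna`, `gene` (unique pairs).
#' @export
read_targets <- function(path, gene_universe = NULL) {
  if (!file.exists(path)) stop_usage("target table not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop_data("%s: expected two columns (mirna, gene)", path)
  pairs <- data.frame(mirna = df[[1]], gene = df[[2]], stringsAsFactors = FALSE)
  if (any(pairs$mirna == "" | pairs$gene == ""))
    stop_data("%s: empty id in target pair (line %d)",
              path, which(pairs$mirna == "" | pairs$gene == "")[1] + 1L)
  if (any(pairs$mirna == pairs$gene))
    stop_data("%s: self-pair '%s'", path,
              pairs$mirna[which(pairs$mirna == pairs$gene)[1]])
  pairs <- unique(pairs)
  if (!is.null(gene_universe)) {
    keep <- pairs$gene %in% gene_universe
    dropped <- sum(!keep)
    pairs <- pairs[keep, , drop = FALSE]
    message(sprintf("read_targets: dropped %d pair(s) with genes absent from the expression matrix", dropped))
    if (nrow(pairs) == 0L)
      stop_data("%s: no target pairs remain after restricting to the gene universe; nothing to integrate", path)
  }
  rownames(pairs) <- NULL
  pairs
}

#' Write a miRNA-to-gene target table
#'
#' @param targets Data frame with columns `mirna`, `gene`.
#' @param path Output path (tab-separated, header `mirna  gene`).
#' @return `path`, invisibly.
#' @export
write_targets <- function(targets, path) {
  utils::write.table(targets[, c("mirna", "gene")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
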