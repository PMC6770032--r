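#' Correlate every feature of an expression matrix against age
#'
#' Runs the Spearman rank-correlation test of each feature's expression
#' against continuous age, restricted to the samples of one tissue class.
#' Samples are matched between matrix columns and metadata by id (never by
#' position). Features with constant expression are reported with `rho` and
#' `p` set to `NA` and `method = "undefined"`; they are excluded from any
#' downstream classification. Ties in expression (or, after a warning at
#' read time, in age) switch that feature to mid-ranks with an approximate
#' p-value, flagged in the `ties` column.
#'
#' @param mat Expression matrix (features x samples) with id dimnames.
#' @param samples Sample metadata with `sample_id`, `tissue`, `age_years`.
#' @param tissue Tissue class to correlate within, `"tumor"` or `"normal"`.
#' @param n_exact_max,n_edgeworth_max Branch points of [spearman_p_exact()].
#' @return `data.frame` with one row per feature: `feature_id`, `tissue`,
#'   `n`, `rho`, `p`, `method`, `ties`.
#' @export
correlate_matrix <- function(mat, samples, tissue = c("tumor", "normal"),
                             n_exact_max = 10L, n_edgeworth_max = 1289L) {
  tissue <- match.arg(tissue)
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop_usage("expression matrix must carry feature rownames and sample colnames")
  sel <- samples[samples$tissue == tissue, , drop = FALSE]
  ids <- intersect(colnames(mat), sel$sample_id)
  if (length(ids) == 0L)
    stop_data("no %s samples shared between the expression matrix and the metadata", tissue)
  if (length(ids) < 3L)
    stop_data("need >= 3 %s samples for correlation, found %d", tissue, length(ids))
  age <- sel$age_years[match(ids, sel$sample_id)]
  n <- length(ids)
  sub <- mat[, ids, drop = FALSE]
  age_rank <- rank(age)
  age_tied <- anyDuplicated(age) > 0L

  feats <- rownames(mat)
  rho <- p <- rep(NA_real_, length(feats))
  method <- rep("undefined", length(feats))
  ties <- rep(FALSE, length(feats))
  for (i in seq_along(feats)) {
    x <- sub[i, ]
    rx <- rank(x)
    if (stats::sd(rx) == 0) next  # constant feature: undefined, excluded
    r <- unname(stats::cor(rx, age_rank))
    x_tied <- anyDuplicated(x) > 0L
    rho[i] <- r
    if (x_tied || age_tied) {
      ties[i] <- TRUE
      method[i] <- "t_approx"
      p[i] <- spearman_t_p(r, n)
    } else {
      pe <- spearman_p_exact(r, n, n_exact_max, n_edgeworth_max)
      p[i] <- pe$p_two_sided
      method[i] <- pe$method
    }
  }
  data.frame(feature_id = feats, tissue = tissue, n = n, rho = rho, p = p,
             method = method, ties = ties, stringsAsFactors = FALSE)
}

#' Screening thresholds for the age-correlation screen
#'
#' @param alpha Significance level for the nominal two-sided p (default
#'   0.05). No multiple-testing correction is applied: the screen is
#'   defined on nominal p-values.
#' @param rho_min Minimum correlation magnitude: features are classified
#'   only when `rho > rho_min` or `rho < -rho_min` (strict, default 0.3).
#' @param normal_p_floor Minimum normal-tissue p-value (inclusive) for a
#'   tumor-classified feature to count as a tumor-specific candidate.
#'   Default 0.05; 0.4 is the stricter published alternative and can be set
#'   here.
#' @return A validated list of class `screening_config`.
#' @export
screening_config <- function(alpha = 0.05, rho_min = 0.3,
                             normal_p_floor = 0.05) {
  if (!(alpha > 0 && alpha < 1))
    stop_usage("alpha must lie in (0, 1), got %g", alpha)
  if (!(rho_min >= 0 && rho_min <= 1))
    stop_usage("rho_min must lie in [0, 1], got %g", rho_min)
  if (!(normal_p_floor >= 0 && normal_p_floor < 1))
    stop_usage("normal_p_floor must lie in [0, 1), got %g", normal_p_floor)
  structure(list(alpha = alpha, rho_min = rho_min,
                 normal_p_floor = normal_p_floor),
            class = "screening_config")
}

classify_correlations <- function(results, config) {
  cls <- rep("unclassified", nrow(results))
  ok <- !is.na(results$rho) & !is.na(results$p) & results$p < config$alpha
  cls[ok & results$rho > config$rho_min] <- "positive"
  cls[ok & results$rho < -config$rho_min] <- "negative"
  cls
}

#' Classify age-correlated features and select tumor-specific candidates
#'
#' Partitions features of each tissue class into positively correlated
#' (`rho > rho_min`, `p < alpha`), anti-correlated (`rho < -rho_min`,
#' `p < alpha`) and unclassified sets, then selects the tumor-specific
#' candidates: features classified in tumor whose normal-tissue p-value is
#' at least `normal_p_floor` — age-correlated in the tumor but not in
#' non-neoplastic tissue, hence not attributable to physiological growth.
#' Features absent from the normal results (or with undefined normal p) are
#' ineligible for candidacy and reported separately.
#'
#' @param tumor_results,normal_results Outputs of [correlate_matrix()] for
#'   the two tissue classes over the same feature universe.
#' @param config A [screening_config()].
#' @return Object of class `screening_outcome`: per-tissue classified
#'   tables, the candidate id vector, ineligible features, and a `counts`
#'   list.
#' @export
screen <- function(tumor_results, normal_results,
                   config = screening_config()) {
  if (nrow(tumor_results) == 0L || nrow(normal_results) == 0L)
    stop_data("empty correlation result list")
  tum <- tumor_results
  nor <- normal_results
  tum$class <- classify_correlations(tum, config)
  nor$class <- classify_correlations(nor, config)

  only_tumor <- setdiff(tum$feature_id, nor$feature_id)
  only_normal <- setdiff(nor$feature_id, tum$feature_id)

  normal_p <- nor$p[match(tum$feature_id, nor$feature_id)]
  eligible <- !is.na(normal_p)  # measured in normal tissue with defined p
  cand <- tum$feature_id[tum$class != "unclassified" & eligible &
                           normal_p >= config$normal_p_floor]

  counts <- list(
    tumor_positive = sum(tum$class == "positive"),
    tumor_negative = sum(tum$class == "negative"),
    normal_positive = sum(nor$class == "positive"),
    normal_negative = sum(nor$class == "negative"),
    tumor_specific_candidates = length(cand)
  )
  structure(list(tumor = tum, normal = nor,
                 tumor_specific_candidates = cand,
                 ineligible = list(missing_in_normal = only_tumor,
                                   missing_in_tumor = only_normal),
                 config = config, counts = counts),
            class = "screening_outcome")
}

#' @export
print.screening_outcome <- function(x, ...) {
  cat("Age-correlation screening outcome\n")
  cat(sprintf("  thresholds: |rho| > %g, p < %g, normal p floor >= %g\n",
              x$config$rho_min, x$config$alpha, x$config$normal_p_floor))
  cat(sprintf("  tumor:  %d positively correlated, %d anti-correlated (of %d features)\n",
              x$counts$tumor_positive, x$counts$tumor_negative, nrow(x$tumor)))
  cat(sprintf("  normal: %d positively correlated, %d anti-correlated (of %d features)\n",
              x$counts$normal_positive, x$counts$normal_negative, nrow(x$normal)))
  cat(sprintf("  tumor-specific candidates: %d\n",
              x$counts$tumor_specific_candidates))
  invisible(x)
}

#' Write screening outputs
#'
#' Writes the per-tissue correlation tables (with class column), one-column
#' feature lists for each classified set, the candidate list, and a JSON
#' summary of the counts.
#'
#' @param outcome A `screening_outcome` from [screen()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix, typically the feature kind.
#' @return Named vector of written paths, invisibly.
#' @export
write_screening <- function(outcome, dir, prefix = "mirna") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (tis in c("tumor", "normal")) {
    f <- file.path(dir, sprintf("%s_correlations_%s.tsv", prefix, tis))
    utils::write.table(outcome[[tis]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths[paste0("correlations_", tis)] <- f
    for (cls in c("positive", "negative")) {
      fl <- file.path(dir, sprintf("%s_%s_%s.txt", prefix, tis, cls))
      writeLines(outcome[[tis]]$feature_id[outcome[[tis]]$class == cls], fl)
      paths[paste(tis, cls, sep = "_")] <- fl
    }
  }
  fc <- file.path(dir, sprintf("%s_tumor_specific_candidates.txt", prefix))
  writeLines(outcome$tumor_specific_candidates, fc)
  paths["candidates"] <- fc
  fs <- file.path(dir, sprintf("%s_screening_summary.json", prefix))
  jsonlite::write_json(outcome$counts, fs, auto_unbox = TRUE, pretty = TRUE)
  paths["summary"] <- fs
  invisible(paths)
}
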