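#' Read a tidy qPCR Ct table
#'
#' Comma-separated with columns `sample_id`, `assay_id`, `ct_target`,
#' `ct_reference` and `group` (e.g. PEDS / AYA). Ct values must be positive
#' and finite cycle counts.
#'
#' @param path Path to the CSV file.
#' @return Validated `data.frame`.
#' @export
read_ct <- function(path) {
  if (!file.exists(path)) stop_usage("Ct table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "assay_id", "ct_target", "ct_reference", "group")
  missing <- setdiff(required, colnames(df))
  if (length(missing) > 0L)
    stop_data("%s: missing required column(s): %s", path,
              paste(missing, collapse = ", "))
  ct <- c(df$ct_target, df$ct_reference)
  if (!all(is.finite(ct)) || any(ct <= 0))
    stop_data("%s: Ct values must be positive finite cycle counts", path)
  df
}

#' Relative quantification by the 2^-ddCt method
#'
#' For a sample and a calibrator measured on the same assay, computes
#' `dCt = ct_target - ct_reference` for each, `ddCt = dCt_sample -
#' dCt_calibrator`, and returns the fold change `2^(-ddCt)` of the sample
#' relative to the calibrator (reference-gene normalized).
#'
#' @param sample,calibrator Lists or one-row data frames with `assay_id`,
#'   `ct_target`, `ct_reference`.
#' @return Fold change (positive real; 1 means no change).
#' @examples
#' rec <- list(assay_id = "A", ct_target = 25, ct_reference = 20)
#' ddct_fold_change(rec, rec)  # 1
#' @export
ddct_fold_change <- function(sample, calibrator) {
  if (!identical(as.character(sample$assay_id),
                 as.character(calibrator$assay_id)))
    stop_usage("assay mismatch: sample is '%s', calibrator is '%s'",
               sample$assay_id, calibrator$assay_id)
  dct_s <- sample$ct_target - sample$ct_reference
  dct_c <- calibrator$ct_target - calibrator$ct_reference
  2^(-(dct_s - dct_c))
}

#' Per-assay group fold change from Ct records
#'
#' Summarizes relative quantities per assay between two groups: fold change
#' of `group_a` over `group_b`, computed as `2^-(mean dCt_a - mean dCt_b)`.
#' Averaging dCt within groups (equivalently, taking geometric means of the
#' per-sample relative quantities, the standard aggregation for the 2^-ddCt
#' method) calibrates each assay to the mean dCt of `group_b`. Assays
#' present in only one group are skipped with a warning.
#'
#' @param records Ct `data.frame` as from [read_ct()].
#' @param group_a,group_b Group labels; the returned fold is a/b.
#' @return `data.frame` with `assay_id`, `fold_change`, `n_a`, `n_b`.
#' @export
group_fold_change <- function(records, group_a, group_b) {
  a <- records[records$group == group_a, , drop = FALSE]
  b <- records[records$group == group_b, , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L)
    stop_data("group '%s' or '%s' has no records",
              group_a, group_b)
  assays <- unique(records$assay_id)
  rows <- lapply(assays, function(id) {
    dct_a <- a$ct_target[a$assay_id == id] - a$ct_reference[a$assay_id == id]
    dct_b <- b$ct_target[b$assay_id == id] - b$ct_reference[b$assay_id == id]
    if (length(dct_a) == 0L || length(dct_b) == 0L) {
      warning(sprintf("assay '%s' present in only one group; skipped", id))
      return(NULL)
    }
    data.frame(assay_id = id,
               fold_change = 2^(-(mean(dct_a) - mean(dct_b))),
               n_a = length(dct_a), n_b = length(dct_b),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(assay_id = character(0), fold_change = numeric(0),
                      n_a = integer(0), n_b = integer(0))
  rownames(out) <- NULL
  out
}
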