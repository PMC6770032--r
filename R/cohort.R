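#' Read a clinical cohort table
#'
#' Comma-separated clinical records with at least `sample_id` and
#' `age_group` (PEDS / AYA); any further columns are categorical clinical
#' attributes (gender, histology, primary site, staging, outcome, ...).
#' Missing values stay `NA` and are summarized as their own category.
#'
#' @param path Path to the CSV file.
#' @return `data.frame` of clinical records.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop_usage("clinical table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "age_group") %in% colnames(df)))
    stop_data("%s: required columns sample_id and age_group", path)
  bad <- setdiff(unique(df$age_group), .age_group_levels)
  if (length(bad) > 0L)
    stop_data("%s: unknown age_group '%s'; accepted: %s", path, bad[1],
              paste(.age_group_levels, collapse = ", "))
  df
}

#' Cohort composition table for one clinical attribute
#'
#' Computes the count and percentage of each category of `attribute`,
#' overall and within the PEDS and AYA age groups. Percentages use the
#' column totals as denominators (overall n, PEDS n, AYA n) and are rounded
#' to the nearest integer with ties away from zero — the convention of
#' printed clinical composition tables. `NA` values form their own `"NA"`
#' category.
#'
#' @param records Clinical `data.frame` with an `age_group` column
#'   (PEDS / AYA).
#' @param attribute Name of the categorical column to summarize.
#' @return `data.frame` with one row per category: `category`, `overall_n`,
#'   `overall_pct`, `peds_n`, `peds_pct`, `aya_n`, `aya_pct`.
#' @export
summarize_cohort <- function(records, attribute) {
  if (!attribute %in% colnames(records))
    stop_usage("unknown attribute '%s'; available: %s", attribute,
               paste(setdiff(colnames(records), c("sample_id", "age_group")),
                     collapse = ", "))
  if (!"age_group" %in% colnames(records))
    stop_usage("records must carry an age_group column")
  v <- as.character(records[[attribute]])
  v[is.na(v) | v == ""] <- "NA"
  cats <- unique(v)
  cats <- c(setdiff(cats, "NA"), intersect("NA", cats))  # NA category last
  grp <- records$age_group
  n_all <- length(v)
  n_peds <- sum(grp == "PEDS")
  n_aya <- sum(grp == "AYA")
  rows <- lapply(cats, function(ct) {
    k_all <- sum(v == ct)
    k_peds <- sum(v == ct & grp == "PEDS")
    k_aya <- sum(v == ct & grp == "AYA")
    data.frame(category = ct,
               overall_n = k_all,
               overall_pct = round_half_up(100 * k_all / n_all),
               peds_n = k_peds,
               peds_pct = if (n_peds > 0) round_half_up(100 * k_peds / n_peds) else NA_real_,
               aya_n = k_aya,
               aya_pct = if (n_aya > 0) round_half_up(100 * k_aya / n_aya) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
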