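#' Path to the packaged preterm study-summary table
#'
#' A 14-row CSV transcription of the characteristics table of the nine
#' eligible preterm MRI studies (study id, optional subgroup label, curated
#' birth-cohort id, sample size, mean age at scan, mean/SD of TIV, GMV and
#' WMV in cm^3, gestational age in weeks, birth weight in grams, percent
#' male, year of birth, country, segmentation method). Missing cells in the
#' source table are empty strings. The `cohort_id` column encodes which
#' rows describe the same underlying birth cohort (several Spanish studies
#' share the Barcelona 1982-1994 cohort), which makes the
#' largest-sample-per-cohort deduplication rule executable.
#'
#' @return file path of the packaged CSV.
#' @export
preterm_table_path <- function() {
  system.file("extdata", "preterm_studies.csv", package = "normtraj",
              mustWork = TRUE)
}

study_table_required <- c("study_id", "n", "age_years")
study_table_numeric <- c("n", "age_years", "tiv_mean_cm3", "tiv_sd_cm3",
                         "gmv_mean_cm3", "gmv_sd_cm3", "wmv_mean_cm3",
                         "wmv_sd_cm3", "ga_weeks", "bw_grams", "male_pct")

#' Parse a study-summary table from CSV
#'
#' Reads a comma-separated, UTF-8, header-first table with `"."` decimal
#' separator where empty cells mean missing. Required columns: `study_id`,
#' `n`, `age_years`, and at least one of the three volume-mean columns.
#' Character columns (`group_label`, `cohort_id`, `country`, ...) are kept
#' as given; absent optional columns are added as `NA` so downstream code
#' can rely on the full schema.
#'
#' @param path CSV file path.
#' @return a data.frame of class `study_table`, one row per study group.
#'   Row-level invariant violations (non-positive volumes, grey + white
#'   exceeding intracranial volume, male percentage outside 0-100) do not
#'   abort parsing; they are returned by [validate_study_table()].
#' @export
parse_study_table <- function(path) {
  if (!file.exists(path))
    abort2(paste0("file not found: ", path), "normtraj_io_error")
  raw <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = TRUE,
                    strip.white = TRUE),
    error = function(e) abort2(paste0("empty or unreadable CSV: ",
                                      conditionMessage(e)),
                               "normtraj_empty_input_error"))
  miss <- setdiff(study_table_required, names(raw))
  if (length(miss))
    abort2(paste0("missing required column(s): ", paste(miss, collapse = ", ")),
           "normtraj_schema_error")
  vol_cols <- c("tiv_mean_cm3", "gmv_mean_cm3", "wmv_mean_cm3")
  if (!any(vol_cols %in% names(raw)))
    abort2("need at least one volume column (tiv/gmv/wmv_mean_cm3)",
           "normtraj_schema_error")

  char_cols <- c("study_id", "group_label", "cohort_id", "year_of_birth",
                 "country", "segmentation_method")
  for (col in setdiff(c(char_cols, study_table_numeric), names(raw)))
    raw[[col]] <- rep(NA_character_, nrow(raw))
  out <- raw[c(char_cols, study_table_numeric)]
  out[char_cols] <- lapply(out[char_cols],
                           function(x) ifelse(x == "", NA_character_, x))

  for (col in study_table_numeric) {
    v <- out[[col]]
    blank <- is.na(v) | v == ""
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!blank & is.na(num))
    if (length(bad) && col %in% c("n", "age_years"))
      abort2(sprintf("row %d: non-numeric value '%s' in column '%s'",
                     bad[1], v[bad[1]], col),
             "normtraj_parse_error")
    if (length(bad)) num[bad] <- NA_real_   # optional columns: treat as missing
    out[[col]] <- num
  }
  out$n <- as.integer(out$n)
  class(out) <- c("study_table", "data.frame")
  out
}

#' Check study-group records against their invariants
#'
#' Invariants: `n >= 1`; `age_years > 0`; every present volume positive;
#' `gmv + wmv < tiv` when all three means are present; `male_pct` within
#' 0-100 when present.
#'
#' @param records a `study_table` data.frame.
#' @return data.frame with columns `row`, `study_id`, `problem`; zero rows
#'   when everything checks out.
#' @export
validate_study_table <- function(records) {
  issues <- list()
  note <- function(i, msg)
    issues[[length(issues) + 1L]] <<-
      data.frame(row = i, study_id = records$study_id[i], problem = msg)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (is.na(r$n) || r$n < 1) note(i, "n must be >= 1")
    if (is.na(r$age_years) || r$age_years <= 0) note(i, "age_years must be > 0")
    for (col in c("tiv_mean_cm3", "gmv_mean_cm3", "wmv_mean_cm3",
                  "tiv_sd_cm3", "gmv_sd_cm3", "wmv_sd_cm3"))
      if (!is.na(r[[col]]) && r[[col]] <= 0)
        note(i, paste0(col, " must be > 0"))
    if (!is.na(r$gmv_mean_cm3) && !is.na(r$wmv_mean_cm3) &&
        !is.na(r$tiv_mean_cm3) &&
        r$gmv_mean_cm3 + r$wmv_mean_cm3 >= r$tiv_mean_cm3)
      note(i, "gmv + wmv must be < tiv")
    if (!is.na(r$male_pct) && (r$male_pct < 0 || r$male_pct > 100))
      note(i, "male_pct must be in [0, 100]")
  }
  if (!length(issues))
    return(data.frame(row = integer(), study_id = character(),
                      problem = character()))
  do.call(rbind, issues)
}

check_unit <- function(unit, allowed) {
  if (!is.character(unit) || length(unit) != 1L || !(unit %in% allowed))
    abort2(paste0("unknown unit '", as.character(unit)[1], "'; expected one of ",
                  paste(allowed, collapse = ", ")),
           "normtraj_unit_error")
  unit
}

#' Convert an age to years
#'
#' Ages reported in months are divided by twelve.
#'
#' @param value positive age value(s).
#' @param unit `"years"` or `"months"`.
#' @return age in years.
#' @export
convert_age <- function(value, unit = c("years", "months")) {
  unit <- check_unit(unit[1], c("years", "months"))
  if (any(value <= 0)) abort2("age must be > 0", "normtraj_domain_error")
  if (unit == "months") value / 12 else value
}

#' Convert a volume to cubic centimetres
#'
#' mm^3 are divided by 1000, dm^3 multiplied by 1000.
#'
#' @param value positive volume value(s).
#' @param unit `"cm3"`, `"mm3"` or `"dm3"`.
#' @return volume in cm^3.
#' @export
convert_volume <- function(value, unit = c("cm3", "mm3", "dm3")) {
  unit <- check_unit(unit[1], c("cm3", "mm3", "dm3"))
  if (any(value <= 0)) abort2("volume must be > 0", "normtraj_domain_error")
  switch(unit, cm3 = value, mm3 = value / 1000, dm3 = value * 1000)
}

#' Convert a birth weight to grams
#'
#' @param value positive weight value(s).
#' @param unit `"g"` or `"kg"`.
#' @return weight in grams.
#' @export
convert_weight <- function(value, unit = c("g", "kg")) {
  unit <- check_unit(unit[1], c("g", "kg"))
  if (any(value <= 0)) abort2("weight must be > 0", "normtraj_domain_error")
  if (unit == "kg") value * 1000 else value
}

#' Recover an absolute volume from a ratio of TIV
#'
#' Some studies report only the tissue-to-intracranial ratio; the absolute
#' mean volume is then `ratio * TIV`.
#'
#' @param ratio unitless fraction strictly inside (0, 1).
#' @param tiv_cm3 total intracranial volume in cm^3, positive.
#' @return volume in cm^3.
#' @export
derive_volume_from_ratio <- function(ratio, tiv_cm3) {
  if (any(ratio <= 0) || any(ratio >= 1))
    abort2("ratio must be strictly inside (0, 1)", "normtraj_domain_error")
  if (any(tiv_cm3 <= 0)) abort2("tiv must be > 0", "normtraj_domain_error")
  ratio * tiv_cm3
}

#' Relative volume (tissue volume / TIV)
#'
#' @param vol_cm3 tissue volume in cm^3, positive.
#' @param tiv_cm3 total intracranial volume in cm^3, positive.
#' @return unitless fraction `vol / tiv`; round-trips with
#'   [derive_volume_from_ratio()].
#' @export
compute_relative_volume <- function(vol_cm3, tiv_cm3) {
  if (any(vol_cm3 <= 0) || any(tiv_cm3 <= 0))
    abort2("volumes must be > 0", "normtraj_domain_error")
  vol_cm3 / tiv_cm3
}

#' Filter study groups for eligibility
#'
#' Retains records whose mean age at scan is strictly greater than
#' `min_age_years` (studies of infants under one year are excluded because
#' brain growth is so rapid there that small age differences dominate the
#' volume signal) and which report all three of TIV, GMV and WMV means.
#' Order is preserved; the operation is idempotent.
#'
#' @param records a `study_table` data.frame.
#' @param min_age_years exclusive lower age limit in years (default 1).
#' @return the retained rows, with the excluded rows and their reasons
#'   attached as a data.frame in `attr(, "excluded")` (columns `study_id`,
#'   `group_label`, `reason`).
#' @export
filter_eligible <- function(records, min_age_years = 1.0) {
  reason <- rep(NA_character_, nrow(records))
  miss <- is.na(records$tiv_mean_cm3) | is.na(records$gmv_mean_cm3) |
    is.na(records$wmv_mean_cm3)
  reason[miss] <- "missing measure"
  young <- !is.na(records$age_years) & records$age_years <= min_age_years
  reason[young] <- paste0("age <= ", min_age_years)
  keep <- records[is.na(reason), , drop = FALSE]
  excluded <- data.frame(study_id = records$study_id[!is.na(reason)],
                         group_label = records$group_label[!is.na(reason)],
                         reason = reason[!is.na(reason)])
  attr(keep, "excluded") <- excluded
  keep
}

#' Deduplicate overlapping cohorts by sample size
#'
#' When several studies report on the same birth cohort at the same age,
#' only the study with the larger sample is kept. Records of the same
#' `cohort_id` are clustered by single linkage on `age_years` with gap
#' `age_tolerance_years`; inside a cluster, all records of the study with
#' the largest summed `n` are retained and every other study's records are
#' dropped. Records of the same cohort at distinct ages all survive. Ties
#' on total `n` are broken toward the lexicographically smallest
#' `study_id`, with a warning.
#'
#' @param records a `study_table` data.frame with `cohort_id` populated.
#' @param age_tolerance_years non-negative; default 0 means only exactly
#'   equal mean ages compete.
#' @return the retained rows in their original order.
#' @export
select_largest_per_cohort <- function(records, age_tolerance_years = 0) {
  if (age_tolerance_years < 0)
    abort2("age_tolerance_years must be >= 0", "normtraj_domain_error")
  if (anyNA(records$cohort_id))
    abort2("cohort_id must be populated for every record",
           "normtraj_domain_error")
  keep <- rep(TRUE, nrow(records))
  for (cid in unique(records$cohort_id)) {
    idx <- which(records$cohort_id == cid)
    if (length(idx) < 2L) next
    ord <- idx[order(records$age_years[idx])]
    gaps <- diff(records$age_years[ord]) > age_tolerance_years
    cluster <- split(ord, cumsum(c(0, gaps)))
    for (cl in cluster) {
      studies <- unique(records$study_id[cl])
      if (length(studies) < 2L) next
      tot <- vapply(studies, function(s)
        sum(records$n[cl][records$study_id[cl] == s]), numeric(1))
      best <- studies[tot == max(tot)]
      if (length(best) > 1L) {
        best <- sort(best)[1]
        warning(sprintf(
          "cohort '%s': tie on total n; keeping '%s' (lexicographic)",
          cid, best), call. = FALSE)
      }
      keep[cl[records$study_id[cl] != best]] <- FALSE
    }
  }
  records[keep, , drop = FALSE]
}

#' Summarize a study table
#'
#' @param records a non-empty `study_table` data.frame.
#' @return object of class `cohort_summary`: list with `total_n` (sum of
#'   group sizes), `n_groups` (rows), `n_studies` (distinct `study_id`),
#'   `age_min_years`, `age_max_years`.
#' @export
summarize_cohort <- function(records) {
  if (nrow(records) == 0L)
    abort2("no records to summarize", "normtraj_empty_input_error")
  structure(list(total_n = sum(records$n),
                 n_groups = nrow(records),
                 n_studies = length(unique(records$study_id)),
                 age_min_years = min(records$age_years),
                 age_max_years = max(records$age_years)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(
    "%d subjects in %d groups from %d studies, mean ages %.3g-%.3g years\n",
    x$total_n, x$n_groups, x$n_studies, x$age_min_years, x$age_max_years))
  invisible(x)
}
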