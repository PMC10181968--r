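cohort_required_columns <- function() {
  c("subject_id", "age_years", "sex", "smoking_status", "family_lung_cancer",
    "prior_extrathoracic_cancer", "diameter_mm", "spiculation", "upper_lobe",
    "nodule_type", "nodule_count", "emphysema_on_ct", "mld_hu", "ei_pct",
    "pei_pct", "ei_cc120_pct", "perc15_hu", "bi_pct", "ggoi_pct", "fibi_pct",
    "lung_volume_ml", "wp_pct", "awt_pi10_cm", "malignant")
}

cohort_levels <- list(
  sex = c("male", "female"),
  smoking_status = c("current", "former", "never", "unknown"),
  family_lung_cancer = c("yes", "no", "unknown"),
  nodule_type = c("solid", "part_solid", "ggo")
)

#' Validate a cohort table
#'
#' Checks the documented schema: required columns, unique subject ids,
#' binary outcome, declared categorical levels. Unknown smoking status and
#' family history are legitimate explicit categories, never imputed.
#'
#' @param df data.frame following the cohort schema.
#' @return the validated data.frame (factors normalized), invisibly typed.
#' @export
validate_cohort <- function(df) {
  missing_cols <- setdiff(cohort_required_columns(), names(df))
  if (length(missing_cols))
    stop("cohort table missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id values")
  if (!all(df$malignant %in% c(0L, 1L)))
    stop("outcome 'malignant' must be coded 0 (benign) / 1 (malignant)")
  for (v in names(cohort_levels)) {
    bad <- setdiff(unique(as.character(df[[v]])), cohort_levels[[v]])
    if (length(bad))
      stop("column '", v, "' has undeclared level(s): ",
           paste(bad, collapse = ", "))
  }
  if (any(df$age_years <= 0, na.rm = TRUE)) stop("age_years must be positive")
  if (any(df$diameter_mm <= 0, na.rm = TRUE))
    stop("diameter_mm must be positive")
  for (v in c("prior_extrathoracic_cancer", "spiculation", "upper_lobe",
              "emphysema_on_ct"))
    if (!all(df[[v]] %in% c(0L, 1L)))
      stop("column '", v, "' must be coded 0/1")
  # derived covariate: ever-smoker (current or former); unknown stays missing
  df$ever_smoker <- ifelse(df$smoking_status %in% c("current", "former"), 1L,
                           ifelse(df$smoking_status == "never", 0L, NA_integer_))
  df
}

#' Read a cohort table from CSV
#'
#' @param path CSV with the documented header (see [validate_cohort()]).
#' @return validated data.frame with a derived `ever_smoker` column.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df)
}

#' Write a cohort table to CSV
#' @param df cohort data.frame.
#' @param path output CSV path.
#' @export
write_cohort <- function(df, path) {
  df <- df[, setdiff(names(df), "ever_smoker"), drop = FALSE]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
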