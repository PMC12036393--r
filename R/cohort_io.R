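# Ingestion and validation of lesion-level and patient-level tables.
#
# Column contract: the lesion CSV must carry `patient_id`, `lesion_id`,
# `baseline_volume_mm3` and optionally `followup_volume_mm3`; every other
# numeric column is treated as a radiomic feature. The clinical CSV carries
# survival, histology and response covariates keyed by `patient_id`.

.mirv_reserved_lesion_cols <- c("patient_id", "lesion_id",
                                "baseline_volume_mm3", "followup_volume_mm3")

.mirv_histology_levels <- c("Leiomyosarcoma", "Liposarcoma", "UPS", "Other")
.mirv_recist_levels <- c("PR", "SD", "PD", "NE")

#' Feature column names of a lesion table
#'
#' @param lesions A lesion table as returned by [read_lesion_table()].
#' @return Character vector of radiomic feature column names (all columns
#'   that are not identifiers or volume measurements).
#' @export
lesion_features <- function(lesions) {
  setdiff(colnames(lesions), .mirv_reserved_lesion_cols)
}

#' Read a lesion-level radiomic feature table
#'
#' Reads a CSV with one row per lesion. Mandatory columns are `patient_id`,
#' `lesion_id` and `baseline_volume_mm3`; `followup_volume_mm3` is optional
#' (missing values there mean no follow-up contour for that lesion). Every
#' remaining column is registered as a radiomic feature and must be fully
#' numeric with no missing values.
#'
#' @param path Path to a CSV file with a header row.
#' @return A `data.frame` with identifier columns coerced to character and
#'   feature columns numeric; row order as on disk.
#' @export
read_lesion_table <- function(path) {
  if (!file.exists(path)) {
    stop("lesion table not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("patient_id", "lesion_id", "baseline_volume_mm3")) {
    if (!col %in% colnames(df)) {
      stop("lesion table is missing mandatory column '", col, "'",
           call. = FALSE)
    }
  }
  df$patient_id <- as.character(df$patient_id)
  df$lesion_id <- as.character(df$lesion_id)
  if (!is.numeric(df$baseline_volume_mm3) || anyNA(df$baseline_volume_mm3)) {
    stop("column 'baseline_volume_mm3' must be numeric with no missing values",
         call. = FALSE)
  }
  if ("followup_volume_mm3" %in% colnames(df) &&
      !is.numeric(df$followup_volume_mm3)) {
    stop("column 'followup_volume_mm3' must be numeric", call. = FALSE)
  }
  for (feat in lesion_features(df)) {
    x <- df[[feat]]
    if (!is.numeric(x)) {
      bad <- which(is.na(suppressWarnings(as.numeric(x))))[1]
      stop("non-numeric feature value in column '", feat, "', row ",
           if (is.na(bad)) "?" else bad, call. = FALSE)
    }
    if (anyNA(x)) {
      stop("missing feature value in column '", feat, "', row ",
           which(is.na(x))[1], call. = FALSE)
    }
  }
  df
}

#' Write a lesion table to CSV
#'
#' @param lesions Lesion table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_lesion_table <- function(lesions, path) {
  utils::write.csv(lesions, path, row.names = FALSE)
  invisible(path)
}

#' Read a patient-level clinical table
#'
#' Mandatory columns: `patient_id`, `os_time` (years), `os_event` (1 = death
#' observed, 0 = censored), `histology`, `age`, `performance_status`,
#' `recist`. Optional binary columns `ctdna_pre` and `ctdna_post` carry
#' liquid-biopsy positivity; when absent the liquid-biopsy analyses are
#' simply unavailable.
#'
#' @param path Path to a CSV file with a header row.
#' @return A `data.frame`, one row per patient.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) {
    stop("clinical table not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  mandatory <- c("patient_id", "os_time", "os_event", "histology", "age",
                 "performance_status", "recist")
  for (col in mandatory) {
    if (!col %in% colnames(df)) {
      stop("clinical table is missing mandatory column '", col, "'",
           call. = FALSE)
    }
  }
  df$patient_id <- as.character(df$patient_id)
  if (!is.numeric(df$os_time) || anyNA(df$os_time) || any(df$os_time <= 0)) {
    stop("'os_time' must be numeric and strictly positive", call. = FALSE)
  }
  if (!all(df$os_event %in% c(0, 1))) {
    stop("'os_event' must be 0 (censored) or 1 (death observed)",
         call. = FALSE)
  }
  bad_hist <- setdiff(unique(df$histology), .mirv_histology_levels)
  if (length(bad_hist)) {
    stop("invalid histology value(s): ", paste(bad_hist, collapse = ", "),
         "; expected one of ", paste(.mirv_histology_levels, collapse = ", "),
         call. = FALSE)
  }
  bad_recist <- setdiff(unique(df$recist), .mirv_recist_levels)
  if (length(bad_recist)) {
    stop("invalid RECIST value(s): ", paste(bad_recist, collapse = ", "),
         "; expected one of ", paste(.mirv_recist_levels, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("ctdna_pre", "ctdna_post")) {
    if (col %in% colnames(df) && !all(df[[col]] %in% c(0, 1, NA))) {
      stop("'", col, "' must be binary (0/1) or missing", call. = FALSE)
    }
  }
  df
}

#' Write a clinical table to CSV
#'
#' @param clinical Clinical table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE)
  invisible(path)
}

#' Validate a cohort
#'
#' Checks every invariant of the lesion and clinical contracts and returns a
#' report rather than raising: duplicate keys, non-positive volumes, missing
#' feature values, invalid categorical levels, non-positive survival times.
#' Lesion-table patients absent from the clinical table are reported as
#' warnings only — they still participate in heterogeneity and response
#' scoring but drop out of the association and survival stages.
#'
#' @param lesions Lesion table.
#' @param clinical Clinical table.
#' @return An object of class `mirv_validation`: a list with `errors`
#'   (data.frame of record key and violated rule), `warnings` (character),
#'   `n_patients` and `n_lesions`.
#' @export
validate_cohort <- function(lesions, clinical) {
  errors <- list()
  warnings <- character()
  add_error <- function(key, rule) {
    errors[[length(errors) + 1L]] <<- data.frame(key = key, rule = rule,
                                                 stringsAsFactors = FALSE)
  }

  key <- paste(lesions$patient_id, lesions$lesion_id, sep = ":")
  dup <- unique(key[duplicated(key)])
  for (k in dup) add_error(k, "duplicated (patient_id, lesion_id) key")

  bad_v0 <- which(!is.finite(lesions$baseline_volume_mm3) |
                    lesions$baseline_volume_mm3 <= 0)
  for (i in bad_v0) add_error(key[i], "baseline_volume_mm3 must be > 0")

  if ("followup_volume_mm3" %in% colnames(lesions)) {
    v1 <- lesions$followup_volume_mm3
    bad_v1 <- which(!is.na(v1) & v1 <= 0)
    for (i in bad_v1) add_error(key[i], "followup_volume_mm3 must be > 0 when present")
  }

  for (feat in lesion_features(lesions)) {
    miss <- which(is.na(lesions[[feat]]))
    for (i in miss) add_error(key[i], paste0("missing value in feature '", feat, "'"))
  }

  dup_pat <- unique(clinical$patient_id[duplicated(clinical$patient_id)])
  for (p in dup_pat) add_error(p, "duplicated patient_id in clinical table")
  bad_t <- which(!is.finite(clinical$os_time) | clinical$os_time <= 0)
  for (i in bad_t) add_error(clinical$patient_id[i], "os_time must be > 0")
  bad_e <- which(!clinical$os_event %in% c(0, 1))
  for (i in bad_e) add_error(clinical$patient_id[i], "os_event must be 0 or 1")
  bad_h <- which(!clinical$histology %in% .mirv_histology_levels)
  for (i in bad_h) add_error(clinical$patient_id[i], "invalid histology level")
  bad_r <- which(!clinical$recist %in% .mirv_recist_levels)
  for (i in bad_r) add_error(clinical$patient_id[i], "invalid RECIST level")

  orphans <- setdiff(unique(lesions$patient_id), clinical$patient_id)
  if (length(orphans)) {
    warnings <- c(warnings, paste0(
      length(orphans), " lesion-table patient(s) absent from clinical table ",
      "(excluded from association/survival stages): ",
      paste(utils::head(orphans, 5), collapse = ", "),
      if (length(orphans) > 5) ", ..." else ""))
  }
  childless <- setdiff(clinical$patient_id, unique(lesions$patient_id))
  if (length(childless)) {
    warnings <- c(warnings, paste0(
      length(childless), " clinical patient(s) have no lesions in the lesion table"))
  }

  structure(list(
    errors = if (length(errors)) do.call(rbind, errors)
             else data.frame(key = character(), rule = character(),
                             stringsAsFactors = FALSE),
    warnings = warnings,
    n_patients = length(unique(lesions$patient_id)),
    n_lesions = nrow(lesions)
  ), class = "mirv_validation")
}

#' @export
print.mirv_validation <- function(x, ...) {
  cat("Cohort validation:", x$n_patients, "patients,", x$n_lesions, "lesions\n")
  cat("  errors:  ", nrow(x$errors), "\n")
  if (nrow(x$errors)) {
    for (i in seq_len(min(nrow(x$errors), 10))) {
      cat("    [", x$errors$key[i], "] ", x$errors$rule[i], "\n", sep = "")
    }
    if (nrow(x$errors) > 10) cat("    ...\n")
  }
  cat("  warnings:", length(x$warnings), "\n")
  for (w in x$warnings) cat("    ", w, "\n", sep = "")
  invisible(x)
}

#' Restrict a lesion table to multi-metastatic patients
#'
#' Keeps exactly the patients contributing at least `min_lesions` lesions —
#' the per-patient heterogeneity score is undefined for single-lesion
#' patients. Row order is preserved; the operation is idempotent.
#'
#' @param lesions Lesion table.
#' @param min_lesions Minimum number of lesions per retained patient
#'   (default 2).
#' @return Filtered lesion table.
#' @export
filter_multimetastatic <- function(lesions, min_lesions = 2) {
  if (!is.numeric(min_lesions) || length(min_lesions) != 1 ||
      min_lesions < 1 || min_lesions != round(min_lesions)) {
    stop("'min_lesions' must be a positive integer", call. = FALSE)
  }
  if (nrow(lesions) == 0) return(lesions)
  counts <- table(lesions$patient_id)
  keep <- names(counts)[counts >= min_lesions]
  out <- lesions[lesions$patient_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) {
    warning("no patient has >= ", min_lesions, " lesions; result is empty",
            call. = FALSE)
  }
  out
}

#' Build a lesion-by-feature matrix from a lesion table
#'
#' @param lesions Lesion table.
#' @return Numeric matrix, one row per lesion in table order; row names are
#'   `lesion_id`, and the matching patient ids are attached as attribute
#'   `patient_id`.
#' @export
lesion_feature_matrix <- function(lesions) {
  feats <- lesion_features(lesions)
  if (!length(feats)) stop("lesion table has no feature columns", call. = FALSE)
  M <- as.matrix(lesions[, feats, drop = FALSE])
  rownames(M) <- lesions$lesion_id
  attr(M, "patient_id") <- lesions$patient_id
  M
}
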