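# Lesion-level volumetric response, per-patient response range,
# tumor-specific response classification (TSRC), and the baseline-volume
# control metrics used to separate heterogeneity from tumor burden.

#' Percent change in lesion volume
#'
#' @param v0 Baseline volume (mm^3), strictly positive.
#' @param v1 Follow-up volume (mm^3), non-negative.
#' @return `100 * (v1 - v0) / v0`. Vectorized.
#' @export
percent_volume_change <- function(v0, v1) {
  if (any(!is.finite(v0) | v0 <= 0)) {
    stop("baseline volume must be > 0", call. = FALSE)
  }
  if (any(!is.finite(v1) | v1 < 0)) {
    stop("follow-up volume must be >= 0", call. = FALSE)
  }
  100 * (v1 - v0) / v0
}

#' Range of volumetric response across a patient's lesions
#'
#' @param changes Percent volume changes, one per lesion (>= 1).
#' @return `max(changes) - min(changes)`, in percent; 0 for a single lesion.
#' @export
response_range <- function(changes) {
  if (!length(changes)) stop("no volume changes supplied", call. = FALSE)
  max(changes) - min(changes)
}

#' Tumor-specific response classification (TSRC)
#'
#' Classifies a patient as Complete Tumor Response (1) or Non-/Partial
#' Tumor Response (0) from per-lesion percent volume changes against a
#' threshold (default 33%). Two directional conventions are supported:
#'
#' * `"reduction"` (default): a lesion responds iff it shrank by at least
#'   the threshold (`change <= -threshold`); Complete requires every lesion
#'   to respond.
#' * `"growth"`: a lesion fails iff it grew beyond the threshold
#'   (`change > +threshold`); Complete requires no lesion to fail.
#'
#' The convention in force is recorded in the run manifest; the two readings
#' differ for patients whose lesions all stayed within `(-threshold,
#' +threshold]`.
#'
#' @param changes Percent volume changes, one per lesion.
#' @param threshold Positive percent threshold (default 33).
#' @param convention `"reduction"` or `"growth"`.
#' @return 0 or 1.
#' @export
classify_tsrc <- function(changes, threshold = 33,
                          convention = c("reduction", "growth")) {
  convention <- match.arg(convention)
  if (!length(changes)) stop("no volume changes supplied", call. = FALSE)
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    stop("'threshold' must be a positive percentage", call. = FALSE)
  }
  if (convention == "reduction") {
    as.integer(all(changes <= -threshold))
  } else {
    as.integer(all(changes <= threshold))
  }
}

#' Baseline-volume control metrics
#'
#' Three per-patient summaries of baseline tumor burden used as controls in
#' the association analysis: the range (largest minus smallest lesion), the
#' sample standard deviation (0 for a single lesion), and the total volume.
#'
#' @param volumes Baseline volumes (mm^3), all strictly positive.
#' @return List with `range`, `sd` and `total`, all in mm^3.
#' @export
baseline_volume_metrics <- function(volumes) {
  if (!length(volumes)) stop("no volumes supplied", call. = FALSE)
  if (any(!is.finite(volumes) | volumes <= 0)) {
    stop("baseline volumes must be > 0", call. = FALSE)
  }
  list(range = max(volumes) - min(volumes),
       sd = if (length(volumes) > 1) stats::sd(volumes) else 0,
       total = sum(volumes))
}

#' Per-patient response table for a cohort
#'
#' Computes, for every patient in the lesion table: percent volume change
#' per evaluable lesion, the response range, the TSRC label, and the three
#' baseline-volume control metrics. Lesions lacking a follow-up volume are
#' dropped from the response computation with a warning; baseline metrics
#' use all lesions. Patients with zero evaluable lesions are excluded from
#' the output (they fall outside the volumetric-response subset).
#'
#' @param lesions Lesion table with `followup_volume_mm3`.
#' @param threshold,convention Passed to [classify_tsrc()].
#' @return A `data.frame` with one row per evaluable patient: `patient_id`,
#'   `n_lesions`, `n_evaluable`, `response_range`, `tsrc`, `baseline_range`,
#'   `baseline_sd`, `baseline_total`.
#' @export
cohort_response <- function(lesions, threshold = 33,
                            convention = c("reduction", "growth")) {
  convention <- match.arg(convention)
  if (!"followup_volume_mm3" %in% colnames(lesions)) {
    stop("lesion table has no 'followup_volume_mm3' column", call. = FALSE)
  }
  n_missing <- sum(is.na(lesions$followup_volume_mm3))
  if (n_missing > 0) {
    warning(n_missing, " lesion(s) without follow-up volume dropped from ",
            "response computation", call. = FALSE)
  }
  pats <- unique(lesions$patient_id)
  rows <- lapply(pats, function(p) {
    sub <- lesions[lesions$patient_id == p, , drop = FALSE]
    base <- baseline_volume_metrics(sub$baseline_volume_mm3)
    ev <- !is.na(sub$followup_volume_mm3)
    if (!any(ev)) return(NULL)
    ch <- percent_volume_change(sub$baseline_volume_mm3[ev],
                                sub$followup_volume_mm3[ev])
    data.frame(patient_id = p,
               n_lesions = nrow(sub),
               n_evaluable = sum(ev),
               response_range = response_range(ch),
               tsrc = classify_tsrc(ch, threshold, convention),
               baseline_range = base$range,
               baseline_sd = base$sd,
               baseline_total = base$total,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    warning("no patient has an evaluable lesion; response table is empty",
            call. = FALSE)
    return(data.frame(patient_id = character(), n_lesions = integer(),
                      n_evaluable = integer(), response_range = numeric(),
                      tsrc = integer(), baseline_range = numeric(),
                      baseline_sd = numeric(), baseline_total = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
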