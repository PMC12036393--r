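# End-to-end pipeline: (simulate | ingest) -> validate -> filter ->
# reduce -> heterogeneity scores -> response -> associations -> survival,
# with a JSON run manifest recording every configurable decision.

#' Pipeline configuration
#'
#' @param lesions_path,clinical_path Input CSVs (ignored when `simulate`
#'   is supplied).
#' @param simulate Optional [synthetic_config()]; when present the cohort
#'   is generated instead of read.
#' @param min_lesions Multi-metastatic filter threshold.
#' @param vol_tau,corr_tau Feature-reduction cutoffs.
#' @param standardize Z-score features before heterogeneity scoring.
#' @param tsrc_threshold,tsrc_convention Response classification settings.
#' @param fdr_alpha Display cutoff on FDR-adjusted associations.
#' @param mirv_var Heterogeneity score used in survival models.
#' @param interaction Covariate interacted with the score in the Cox model
#'   (`NULL` to drop the interaction).
#' @param min_subgroup Minimum stratum size for subgroup log-rank tests.
#' @return A `mirv_run_config` list.
#' @export
run_config <- function(lesions_path = NULL, clinical_path = NULL,
                       simulate = NULL, min_lesions = 2,
                       vol_tau = 0.1, corr_tau = 0.7, standardize = TRUE,
                       tsrc_threshold = 33, tsrc_convention = "reduction",
                       fdr_alpha = 0.05,
                       mirv_var = "mirv_max_dissimilarity",
                       interaction = "histology", min_subgroup = 20) {
  if (is.null(simulate) &&
      (is.null(lesions_path) || is.null(clinical_path))) {
    stop("supply either input paths or a simulation config", call. = FALSE)
  }
  structure(list(lesions_path = lesions_path,
                 clinical_path = clinical_path, simulate = simulate,
                 min_lesions = min_lesions, vol_tau = vol_tau,
                 corr_tau = corr_tau, standardize = standardize,
                 tsrc_threshold = tsrc_threshold,
                 tsrc_convention = tsrc_convention, fdr_alpha = fdr_alpha,
                 mirv_var = mirv_var, interaction = interaction,
                 min_subgroup = min_subgroup),
            class = "mirv_run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes every stage on either supplied CSV inputs or a simulated
#' cohort, writes all stage outputs as CSV plus a JSON run manifest to
#' `out_dir`, and returns the in-memory results. Outputs are byte-stable:
#' rerunning with the same configuration and seed reproduces every file
#' bit-identically.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed (used by the simulation stage).
#' @return Invisibly, a list with all stage results and the `manifest`.
#' @export
run_pipeline <- function(config, out_dir, seed = 1) {
  if (!inherits(config, "mirv_run_config")) {
    stop("'config' must come from run_config()", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    tool = "mirv", version = as.character(utils::packageVersion("mirv")),
    seed = seed,
    parameters = list(
      min_lesions = config$min_lesions, vol_tau = config$vol_tau,
      corr_tau = config$corr_tau, standardize = config$standardize,
      tsrc_threshold = config$tsrc_threshold,
      tsrc_convention = config$tsrc_convention,
      fdr_method = "BH", fdr_alpha = config$fdr_alpha,
      mirv_var = config$mirv_var,
      interaction = if (is.null(config$interaction)) "none"
                    else config$interaction,
      min_subgroup = config$min_subgroup,
      cox_ties = "efron", km_split = "median",
      reference_levels = list(histology = "Other", recist = "SD")))

  if (!is.null(config$simulate)) {
    sim <- .stage("simulate", generate_cohort(config$simulate, seed = seed))
    lesions <- sim$lesions
    clinical <- sim$clinical
    write_lesion_table(lesions, file.path(out_dir, "lesions.csv"))
    write_clinical_table(clinical, file.path(out_dir, "clinical.csv"))
    manifest$inputs <- list(mode = "simulated",
                            n_patients = config$simulate$n_patients)
  } else {
    lesions <- .stage("ingest", read_lesion_table(config$lesions_path))
    clinical <- .stage("ingest", read_clinical_table(config$clinical_path))
    manifest$inputs <- list(mode = "files",
                            lesions = config$lesions_path,
                            clinical = config$clinical_path)
  }

  report <- .stage("validate", validate_cohort(lesions, clinical))
  if (nrow(report$errors) > 0) {
    stop("pipeline stage 'validate' failed: ", nrow(report$errors),
         " cohort invariant violation(s); first: [",
         report$errors$key[1], "] ", report$errors$rule[1], call. = FALSE)
  }
  manifest$validation <- list(n_patients = report$n_patients,
                              n_lesions = report$n_lesions,
                              warnings = as.list(report$warnings))

  lesions_mm <- .stage("filter",
                       filter_multimetastatic(lesions, config$min_lesions))
  manifest$filter <- list(n_lesions_in = nrow(lesions),
                          n_lesions_out = nrow(lesions_mm),
                          n_patients_out =
                            length(unique(lesions_mm$patient_id)))

  M <- .stage("reduce", lesion_feature_matrix(lesions_mm))
  red <- .stage("reduce", reduce_features(
    M, lesions_mm$baseline_volume_mm3,
    vol_tau = config$vol_tau, corr_tau = config$corr_tau))
  manifest$reduction <- list(
    n_features_in = red$report$n_input,
    n_features_retained = red$report$n_retained,
    removed_variance = as.list(red$report$variance$feature),
    removed_volume = as.list(red$report$volume$feature),
    removed_correlation = as.list(red$report$correlation$feature),
    retained = as.list(red$report$retained))
  reduced_df <- data.frame(patient_id = lesions_mm$patient_id,
                           lesion_id = lesions_mm$lesion_id,
                           red$matrix, stringsAsFactors = FALSE,
                           check.names = FALSE)
  utils::write.csv(reduced_df, file.path(out_dir, "reduced_features.csv"),
                   row.names = FALSE)

  mirv_tab <- .stage("score", suppressWarnings(cohort_mirv(
    red$matrix, patient_id = lesions_mm$patient_id,
    lesion_id = lesions_mm$lesion_id,
    standardize = config$standardize)))
  utils::write.csv(mirv_tab, file.path(out_dir, "mirv.csv"),
                   row.names = FALSE)

  resp <- NULL
  if ("followup_volume_mm3" %in% colnames(lesions_mm)) {
    resp <- .stage("response", suppressWarnings(cohort_response(
      lesions_mm, threshold = config$tsrc_threshold,
      convention = config$tsrc_convention)))
    utils::write.csv(resp, file.path(out_dir, "response.csv"),
                     row.names = FALSE)
  }

  assoc_vol <- NULL
  assoc_lb <- NULL
  if (!is.null(resp) && nrow(resp) > 0) {
    assoc_vol <- .stage("associate", association_matrix(
      association_data(mirv_tab, resp, subset = "volumetric"),
      variables = c("mirv_max_distance", "mirv_max_dissimilarity",
                    "response_range", "tsrc", "baseline_range",
                    "baseline_sd", "baseline_total"),
      alpha = config$fdr_alpha))
    utils::write.csv(assoc_vol, file.path(out_dir, "assoc_volumetric.csv"),
                     row.names = FALSE)
    if (all(c("ctdna_pre", "ctdna_post") %in% colnames(clinical))) {
      assoc_lb <- .stage("associate", association_matrix(
        association_data(mirv_tab, resp, clinical,
                         subset = "liquid_biopsy"),
        variables = c("mirv_max_distance", "mirv_max_dissimilarity",
                      "ctdna_pre", "ctdna_post", "baseline_range",
                      "baseline_sd", "baseline_total"),
        alpha = config$fdr_alpha))
      utils::write.csv(assoc_lb,
                       file.path(out_dir, "assoc_liquid_biopsy.csv"),
                       row.names = FALSE)
    }
  }

  surv_tab <- .stage("survival", survival_data(mirv_tab, clinical, resp))
  cox <- .stage("survival", fit_cox(
    surv_tab, mirv_var = config$mirv_var,
    interaction = config$interaction))
  utils::write.csv(cox$table, file.path(out_dir, "cox.csv"),
                   row.names = FALSE)
  subgroups <- .stage("survival", suppressWarnings(subgroup_analysis(
    surv_tab, mirv_var = config$mirv_var,
    min_size = config$min_subgroup)))
  utils::write.csv(subgroups$table, file.path(out_dir, "subgroups.csv"),
                   row.names = FALSE)

  manifest$counts <- list(
    n_scored_patients = nrow(mirv_tab),
    n_response_patients = if (is.null(resp)) 0 else nrow(resp),
    n_survival_patients = cox$n, n_events = cox$events)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(lesions = lesions, clinical = clinical,
                 validation = report, reduced = red, mirv = mirv_tab,
                 response = resp, assoc_volumetric = assoc_vol,
                 assoc_liquid_biopsy = assoc_lb, cox = cox,
                 subgroups = subgroups, manifest = manifest))
}
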