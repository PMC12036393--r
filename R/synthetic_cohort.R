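# Synthetic multi-metastatic cohort generator with known ground truth.
#
# Each patient carries a latent heterogeneity level sigma_p that disperses
# their lesions' signal features around a patient-specific phenotype
# center; lesion response, ctDNA positivity and (within one histology)
# survival hazard are tied to these latents, so every downstream stage has
# a recoverable ground truth. Nuisance features (volume proxies,
# near-constant columns, duplicates) are planted so the reduction pipeline
# has exactly those to remove.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate a multi-metastatic soft-tissue sarcoma cohort: lesion
#' counts with median 2 and interquartile range \[2, 3\]; a histology
#' mixture of 41% leiomyosarcoma, 14% liposarcoma, 12% undifferentiated
#' pleomorphic sarcoma and 33% other; log-normal baseline volumes;
#' exponential overall survival with ~72% observed events; and lesion
#' volume kinetics that yield a mix of complete, partial and non-responding
#' patients under a 33% shrinkage rule.
#'
#' @param n_patients Number of patients.
#' @param lesion_count_values,lesion_count_probs Support and probabilities
#'   of the per-patient lesion count (minimum 2).
#' @param n_signal_features Latent signal features per lesion.
#' @param n_duplicate Number of leading signal features duplicated verbatim
#'   (redundancy-filter targets).
#' @param n_near_constant Near-constant nuisance columns (variance-filter
#'   targets).
#' @param sigma_range Range of the per-patient heterogeneity level
#'   sigma_p ~ Uniform(min, max).
#' @param center_sd Standard deviation of the patient phenotype centers.
#' @param response_center_sd Standard deviation of the phenotype center
#'   along the response-sensitivity axis (the first signal feature). Kept
#'   small relative to `center_sd` so that mixed treatment response arises
#'   from within-patient lesion dispersion (the heterogeneity of interest)
#'   rather than from between-patient baseline differences.
#' @param feature_scale_base Signal feature j is emitted at scale
#'   `base^(j-1)`, mimicking the heterogeneous scales of radiomic features.
#' @param volume_meanlog,volume_sdlog Log-normal baseline volume (mm^3).
#' @param response_intercept,response_slope Lesion-level logistic response
#'   model on the first latent phenotype coordinate.
#' @param dv_responder_mean,dv_responder_sd,dv_nonresponder_mean,dv_nonresponder_sd
#'   Normal emission laws (percent volume change) for responding and
#'   non-responding lesions.
#' @param ctdna_intercept,ctdna_volume_coef,ctdna_sigma_coef Logistic model
#'   for post-treatment ctDNA positivity on centered log total volume and
#'   sigma_p; the pre-treatment label uses the same model without the
#'   sigma term.
#' @param baseline_hazard Exponential death hazard per year.
#' @param mirv_hazard_beta Log-hazard increment per unit sigma_p, applied
#'   only within `hazard_histology`.
#' @param hazard_histology Histology level carrying the heterogeneity
#'   effect.
#' @param censor_rate Exponential censoring hazard per year.
#' @param admin_censor_years Administrative censoring horizon.
#' @param histology_probs Named histology mixture (must sum to 1).
#' @return A validated `mirv_synthetic_config` list.
#' @export
synthetic_config <- function(
    n_patients = 200,
    lesion_count_values = 2:6,
    lesion_count_probs = c(0.55, 0.25, 0.12, 0.05, 0.03),
    n_signal_features = 5,
    n_duplicate = 2,
    n_near_constant = 1,
    sigma_range = c(0.1, 2.0),
    center_sd = 1,
    response_center_sd = 0.2,
    feature_scale_base = 3,
    volume_meanlog = 8.5,
    volume_sdlog = 1,
    response_intercept = 4,
    response_slope = 8,
    dv_responder_mean = -50, dv_responder_sd = 10,
    dv_nonresponder_mean = 10, dv_nonresponder_sd = 15,
    ctdna_intercept = -0.5, ctdna_volume_coef = 0.8, ctdna_sigma_coef = 0.8,
    baseline_hazard = 0.46,
    mirv_hazard_beta = 0.8,
    hazard_histology = "Leiomyosarcoma",
    censor_rate = 0.18,
    admin_censor_years = 6,
    histology_probs = c(Leiomyosarcoma = 0.41, Liposarcoma = 0.14,
                        UPS = 0.12, Other = 0.33)) {
  cfg <- list(n_patients = n_patients,
              lesion_count_values = lesion_count_values,
              lesion_count_probs = lesion_count_probs,
              n_signal_features = n_signal_features,
              n_duplicate = n_duplicate,
              n_near_constant = n_near_constant,
              sigma_range = sigma_range, center_sd = center_sd,
              response_center_sd = response_center_sd,
              feature_scale_base = feature_scale_base,
              volume_meanlog = volume_meanlog, volume_sdlog = volume_sdlog,
              response_intercept = response_intercept,
              response_slope = response_slope,
              dv_responder_mean = dv_responder_mean,
              dv_responder_sd = dv_responder_sd,
              dv_nonresponder_mean = dv_nonresponder_mean,
              dv_nonresponder_sd = dv_nonresponder_sd,
              ctdna_intercept = ctdna_intercept,
              ctdna_volume_coef = ctdna_volume_coef,
              ctdna_sigma_coef = ctdna_sigma_coef,
              baseline_hazard = baseline_hazard,
              mirv_hazard_beta = mirv_hazard_beta,
              hazard_histology = hazard_histology,
              censor_rate = censor_rate,
              admin_censor_years = admin_censor_years,
              histology_probs = histology_probs)
  validate_synthetic_config(cfg)
  structure(cfg, class = "mirv_synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  stopifnot_cfg <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  stopifnot_cfg(cfg$n_patients >= 1, "n_patients must be >= 1")
  stopifnot_cfg(length(cfg$lesion_count_values) ==
                  length(cfg$lesion_count_probs),
                "lesion count support and probabilities differ in length")
  stopifnot_cfg(all(cfg$lesion_count_values >= 2),
                "lesion counts must be >= 2")
  stopifnot_cfg(all(cfg$lesion_count_probs >= 0) &&
                  abs(sum(cfg$lesion_count_probs) - 1) < 1e-8,
                "lesion count probabilities must be non-negative and sum to 1")
  stopifnot_cfg(cfg$n_signal_features >= 1, "need >= 1 signal feature")
  stopifnot_cfg(cfg$n_duplicate >= 0 &&
                  cfg$n_duplicate <= cfg$n_signal_features,
                "n_duplicate must be between 0 and n_signal_features")
  stopifnot_cfg(cfg$n_near_constant >= 0, "n_near_constant must be >= 0")
  stopifnot_cfg(length(cfg$sigma_range) == 2 &&
                  cfg$sigma_range[1] <= cfg$sigma_range[2] &&
                  cfg$sigma_range[1] >= 0,
                "sigma_range must be ordered and non-negative")
  stopifnot_cfg(all(cfg$histology_probs >= 0) &&
                  abs(sum(cfg$histology_probs) - 1) < 1e-8,
                "histology mixture must be non-negative and sum to 1")
  stopifnot_cfg(!is.null(names(cfg$histology_probs)) &&
                  all(names(cfg$histology_probs) %in%
                        .mirv_histology_levels),
                "histology mixture names must be valid histology levels")
  stopifnot_cfg(cfg$baseline_hazard > 0, "baseline_hazard must be > 0")
  stopifnot_cfg(cfg$censor_rate >= 0, "censor_rate must be >= 0")
  stopifnot_cfg(cfg$admin_censor_years > 0, "admin horizon must be > 0")
  stopifnot_cfg(cfg$center_sd >= 0 && cfg$response_center_sd >= 0,
                "phenotype-center SDs must be >= 0")
  stopifnot_cfg(cfg$dv_responder_sd > 0 && cfg$dv_nonresponder_sd > 0,
                "volume-change emission SDs must be > 0")
  invisible(cfg)
}

# Deterministic per-patient substream seed: adding patient n+1 never
# perturbs patients 1..n, and every draw flows from the single base seed.
.patient_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 1e6) * 2048 + 7919 * i) %% 2147483647L
}

#' Generate a synthetic multi-metastatic cohort
#'
#' Per patient: a histology drawn from the mixture; a heterogeneity level
#' sigma_p ~ Uniform(sigma_range); a phenotype center mu_p; lesion signal
#' vectors `mu_p + sigma_p * eps` with independent standard-normal noise;
#' log-normal baseline volumes independent of the signal features by
#' construction; nuisance features (log- and square-root-volume proxies,
#' near-constant columns, verbatim duplicates of leading signal features);
#' lesion response flags from a logistic model on the first latent
#' coordinate with percent volume changes from responder/non-responder
#' emission laws; binary ctDNA labels from a logistic model on tumor burden
#' (and sigma_p post-treatment); and exponential survival whose hazard is
#' multiplied by `exp(beta * sigma_p)` only within the designated
#' histology, with independent exponential plus administrative censoring.
#'
#' The same `(config, seed)` pair reproduces the output bit-identically.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer base seed.
#' @return List with `lesions` (lesion table), `clinical` (clinical table)
#'   and `truth` (list of per-patient and per-lesion generative parameters).
#' @export
generate_cohort <- function(config = synthetic_config(), seed = 1) {
  validate_synthetic_config(config)
  cfg <- config
  k <- cfg$n_signal_features
  scales <- cfg$feature_scale_base^(seq_len(k) - 1)

  lesion_rows <- vector("list", cfg$n_patients)
  clinical_rows <- vector("list", cfg$n_patients)
  truth_pat <- vector("list", cfg$n_patients)
  truth_les <- vector("list", cfg$n_patients)

  for (i in seq_len(cfg$n_patients)) {
    set.seed(.patient_seed(seed, i))
    pid <- sprintf("P%04d", i)
    n_les <- cfg$lesion_count_values[
      sample.int(length(cfg$lesion_count_values), 1,
                 prob = cfg$lesion_count_probs)]
    hist_p <- sample(names(cfg$histology_probs), 1,
                     prob = cfg$histology_probs)
    sigma <- stats::runif(1, cfg$sigma_range[1], cfg$sigma_range[2])
    mu <- stats::rnorm(k, 0, cfg$center_sd)
    mu[1] <- stats::rnorm(1, 0, cfg$response_center_sd)
    eps <- matrix(stats::rnorm(n_les * k), n_les, k)
    latent <- sweep(eps * sigma, 2, mu, "+")
    vol <- stats::rlnorm(n_les, cfg$volume_meanlog, cfg$volume_sdlog)

    responder <- stats::rbinom(n_les, 1, stats::plogis(
      cfg$response_intercept + cfg$response_slope * latent[, 1]))
    dv <- ifelse(responder == 1,
                 stats::rnorm(n_les, cfg$dv_responder_mean,
                              cfg$dv_responder_sd),
                 stats::rnorm(n_les, cfg$dv_nonresponder_mean,
                              cfg$dv_nonresponder_sd))
    dv <- pmax(dv, -99.9)
    vol_fu <- vol * (1 + dv / 100)

    total_vol <- sum(vol)
    lp_burden <- cfg$ctdna_intercept +
      cfg$ctdna_volume_coef * (log(total_vol) - 9)
    ctdna_pre <- stats::rbinom(1, 1, stats::plogis(lp_burden))
    ctdna_post <- stats::rbinom(1, 1, stats::plogis(
      lp_burden + cfg$ctdna_sigma_coef * sigma))

    mult <- exp(cfg$mirv_hazard_beta * sigma *
                  (hist_p == cfg$hazard_histology))
    t_death <- stats::rexp(1, cfg$baseline_hazard * mult)
    t_cens <- if (cfg$censor_rate > 0) stats::rexp(1, cfg$censor_rate)
              else Inf
    os_time <- min(t_death, t_cens, cfg$admin_censor_years)
    os_event <- as.integer(t_death <= min(t_cens, cfg$admin_censor_years))

    age <- min(90, max(18, round(stats::rnorm(1, 58, 13))))
    ps <- sample(0:2, 1, prob = c(0.5, 0.4, 0.1))
    recist <- sample(c("PR", "SD", "PD", "NE"), 1,
                     prob = c(0.078, 0.667, 0.250, 0.005))

    feats <- sweep(latent, 2, scales, "*")
    colnames(feats) <- sprintf("signal_%02d", seq_len(k))
    nuis <- cbind(vol_proxy_log = log(vol), vol_proxy_sqrt = sqrt(vol))
    if (cfg$n_near_constant > 0) {
      nc <- matrix(0.5 + stats::rnorm(n_les * cfg$n_near_constant, 0, 1e-6),
                   n_les, cfg$n_near_constant)
      colnames(nc) <- sprintf("near_constant_%02d",
                              seq_len(cfg$n_near_constant))
      nuis <- cbind(nuis, nc)
    }
    if (cfg$n_duplicate > 0) {
      dup <- feats[, seq_len(cfg$n_duplicate), drop = FALSE]
      colnames(dup) <- sprintf("dup_of_signal_%02d",
                               seq_len(cfg$n_duplicate))
    } else {
      dup <- NULL
    }

    lesion_rows[[i]] <- data.frame(
      patient_id = pid,
      lesion_id = sprintf("L%02d", seq_len(n_les)),
      baseline_volume_mm3 = vol,
      followup_volume_mm3 = vol_fu,
      feats, dup, nuis,
      stringsAsFactors = FALSE, check.names = FALSE)

    clinical_rows[[i]] <- data.frame(
      patient_id = pid, os_time = os_time, os_event = os_event,
      histology = hist_p, age = age, performance_status = ps,
      recist = recist, ctdna_pre = ctdna_pre, ctdna_post = ctdna_post,
      stringsAsFactors = FALSE)

    truth_pat[[i]] <- data.frame(
      patient_id = pid, sigma = sigma, histology = hist_p,
      n_lesions = n_les, hazard_multiplier = mult,
      ctdna_linpred = lp_burden, stringsAsFactors = FALSE)
    truth_les[[i]] <- data.frame(
      patient_id = pid, lesion_id = sprintf("L%02d", seq_len(n_les)),
      responder = responder, dv_true = dv, stringsAsFactors = FALSE)
  }

  lesions <- do.call(rbind, lesion_rows)
  clinical <- do.call(rbind, clinical_rows)
  rownames(lesions) <- rownames(clinical) <- NULL
  truth <- structure(list(
    patients = do.call(rbind, truth_pat),
    lesions = do.call(rbind, truth_les),
    config = cfg, seed = seed), class = "mirv_truth")
  rownames(truth$patients) <- rownames(truth$lesions) <- NULL
  list(lesions = lesions, clinical = clinical, truth = truth)
}

#' Summarize the generative ground truth
#'
#' @param truth The `truth` component of [generate_cohort()].
#' @return A `data.frame` with one row per histology: patient count, mean
#'   and SD of the heterogeneity level sigma_p, and the lesion-level
#'   responder rate.
#' @export
summarize_truth <- function(truth) {
  if (is.null(truth$patients) || nrow(truth$patients) == 0) {
    stop("empty truth object", call. = FALSE)
  }
  les <- merge(truth$lesions,
               truth$patients[, c("patient_id", "histology")],
               by = "patient_id")
  hists <- unique(truth$patients$histology)
  out <- do.call(rbind, lapply(hists, function(h) {
    p <- truth$patients[truth$patients$histology == h, ]
    l <- les[les$histology == h, ]
    data.frame(histology = h, n_patients = nrow(p),
               sigma_mean = mean(p$sigma),
               sigma_sd = if (nrow(p) > 1) stats::sd(p$sigma) else 0,
               responder_rate = mean(l$responder),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$n_patients), , drop = FALSE]
  rownames(out) <- NULL
  out
}
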