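test_that("generation is deterministic and insensitive to later patients", {
  cfg <- synthetic_config(n_patients = 25)
  g1 <- generate_cohort(cfg, seed = 71)
  g2 <- generate_cohort(cfg, seed = 71)
  expect_identical(g1$lesions, g2$lesions)
  expect_identical(g1$clinical, g2$clinical)
  expect_identical(g1$truth$patients, g2$truth$patients)

  # adding patients leaves earlier patients' draws untouched
  g_big <- generate_cohort(synthetic_config(n_patients = 40), seed = 71)
  expect_identical(g_big$lesions[g_big$lesions$patient_id %in%
                                   g1$lesions$patient_id, ],
                   g1$lesions)

  expect_false(identical(generate_cohort(cfg, seed = 72)$lesions,
                         g1$lesions))
})

test_that("emitted tables satisfy the cohort contract", {
  g <- generate_cohort(synthetic_config(n_patients = 60), seed = 73)
  rep <- validate_cohort(g$lesions, g$clinical)
  expect_equal(nrow(rep$errors), 0)
  expect_equal(length(rep$warnings), 0)
  # truth keys match the emitted tables exactly
  expect_setequal(g$truth$patients$patient_id, g$clinical$patient_id)
  expect_identical(paste(g$truth$lesions$patient_id,
                         g$truth$lesions$lesion_id),
                   paste(g$lesions$patient_id, g$lesions$lesion_id))
  # configuration errors precede any sampling
  expect_error(synthetic_config(sigma_range = c(2, 1)), "sigma_range")
  expect_error(synthetic_config(histology_probs = c(Other = 0.5)),
               "sum to 1")
  expect_error(synthetic_config(lesion_count_values = 1:3,
                                lesion_count_probs = c(.3, .3, .4)),
               ">= 2")
})

test_that("degenerate heterogeneity collapses all lesion scores to zero", {
  cfg0 <- synthetic_config(n_patients = 12, sigma_range = c(0, 0))
  g0 <- generate_cohort(cfg0, seed = 74)
  feats <- sprintf("signal_%02d", 1:5)
  M <- as.matrix(g0$lesions[, feats])
  mv <- cohort_mirv(M, g0$lesions$patient_id, g0$lesions$lesion_id,
                    standardize = TRUE)
  expect_equal(max(mv$mirv_max_distance), 0, tolerance = 1e-12)
  expect_equal(max(mv$mirv_max_dissimilarity), 0, tolerance = 1e-12)
})

test_that("lesion counts and histology mixture hit their cohort targets", {
  g <- generate_cohort(synthetic_config(n_patients = 600), seed = 75)
  counts <- table(g$lesions$patient_id)
  expect_equal(unname(stats::median(counts)), 2)
  q <- unname(stats::quantile(counts, c(0.25, 0.75), type = 1))
  expect_gte(q[1], 2)
  expect_lte(q[2], 4)

  g1k <- generate_cohort(synthetic_config(n_patients = 1000), seed = 76)
  prop <- table(g1k$clinical$histology) / 1000
  target <- c(Leiomyosarcoma = 0.41, Liposarcoma = 0.14,
              UPS = 0.12, Other = 0.33)
  expect_true(all(abs(prop[names(target)] - target) < 0.05))
})

test_that("truth summaries aggregate per histology", {
  g <- generate_cohort(synthetic_config(n_patients = 80), seed = 77)
  s <- summarize_truth(g$truth)
  expect_setequal(s$histology, unique(g$truth$patients$histology))
  expect_equal(sum(s$n_patients), 80)
  expect_true(all(s$responder_rate >= 0 & s$responder_rate <= 1))

  g_one <- generate_cohort(synthetic_config(
    n_patients = 10, histology_probs = c(Other = 1)), seed = 78)
  expect_equal(nrow(summarize_truth(g_one$truth)), 1)

  expect_error(summarize_truth(list(patients = NULL)), "empty truth")
})

test_that("planted nuisance features are removed and signal recovered", {
  g <- generate_cohort(synthetic_config(n_patients = 100), seed = 79)
  M <- lesion_feature_matrix(g$lesions)
  red <- reduce_features(M, g$lesions$baseline_volume_mm3)
  removed <- c(red$report$variance$feature, red$report$volume$feature,
               red$report$correlation$feature)
  # volume proxies, near-constant and duplicate columns never survive
  expect_true(all(c("vol_proxy_log", "vol_proxy_sqrt", "near_constant_01",
                    "dup_of_signal_01", "dup_of_signal_02") %in% removed))
  expect_true(all(grepl("^signal_", red$report$retained)))
})

test_that("null generative links yield null downstream associations", {
  # With response, ctDNA and hazard decoupled from heterogeneity, the
  # score-response and score-ctDNA associations should be non-significant
  # in >= 90% of replicate cohorts. Lesion counts are held fixed here:
  # max-pairwise scores and all-lesion response conjunctions both depend
  # on the number of lesions, so varying counts induce a real (not
  # spurious) association even when the generative links are off.
  reps <- 100
  nonsig <- matrix(NA, reps, 2)
  for (r in seq_len(reps)) {
    cfg <- synthetic_config(n_patients = 80, response_slope = 0,
                            ctdna_sigma_coef = 0, mirv_hazard_beta = 0,
                            lesion_count_values = 3,
                            lesion_count_probs = 1)
    g <- generate_cohort(cfg, seed = 8000 + r)
    M <- lesion_feature_matrix(g$lesions)
    red <- reduce_features(M, g$lesions$baseline_volume_mm3)
    mv <- suppressWarnings(cohort_mirv(
      red$matrix, patient_id = g$lesions$patient_id,
      lesion_id = g$lesions$lesion_id))
    rs <- suppressWarnings(cohort_response(g$lesions))
    d <- merge(merge(mv, rs, by = "patient_id"), g$clinical,
               by = "patient_id")
    nonsig[r, 1] <- spearman_cor(d$mirv_max_distance, d$tsrc)$p > 0.05
    nonsig[r, 2] <- spearman_cor(d$mirv_max_distance, d$ctdna_post)$p > 0.05
  }
  expect_gte(mean(nonsig[, 1]), 0.90)
  expect_gte(mean(nonsig[, 2]), 0.90)
})
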