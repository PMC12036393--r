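test_that("standardization gives zero mean, unit sample SD, and is idempotent", {
  M <- cbind(a = c(1, 3), b = c(10, 30))
  Z <- standardize_features(M)
  expect_equal(Z[, "a"], c(-1, 1) / sqrt(2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(colMeans(Z)), c(0, 0))
  expect_equal(unname(apply(Z, 2, sd)), c(1, 1))
  expect_equal(standardize_features(Z), Z, tolerance = 1e-12)
  expect_error(standardize_features(cbind(a = c(1, 2), k = c(5, 5))), "k")
})

test_that("pairwise metrics match their closed forms", {
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_distance(c(1, 1, 1), c(2, 2, 2)), sqrt(3))
  expect_equal(euclidean_distance(c(1, 2), c(1, 2)), 0)
  expect_error(euclidean_distance(1:2, 1:3), "length")

  u <- c(1, 2, 3)
  expect_equal(cosine_dissimilarity(u, u), 0)
  expect_equal(cosine_dissimilarity(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_dissimilarity(u, -u), 2)
  expect_equal(cosine_dissimilarity(u, 5.7 * u), 0)   # positive scaling
  expect_error(cosine_dissimilarity(c(0, 0), c(1, 2)), "zero-norm")
})

test_that("per-patient maxima equal the exhaustive pair scan", {
  # two lesions: the maxima are the single pairwise values
  M2 <- rbind(L1 = c(1, 0, 2), L2 = c(0, 1, -1))
  r2 <- patient_mirv(M2)
  expect_equal(r2$mirv_max_distance, euclidean_distance(M2[1, ], M2[2, ]))
  expect_equal(r2$mirv_max_dissimilarity,
               cosine_dissimilarity(M2[1, ], M2[2, ]))
  expect_equal(r2$argmax_pair_distance, c("L1", "L2"))

  set.seed(31)
  M5 <- matrix(rnorm(5 * 7), 5, 7,
               dimnames = list(paste0("L", 1:5), NULL))
  r5 <- patient_mirv(M5)
  o5 <- oracle_patient_mirv(M5)
  expect_equal(r5$mirv_max_distance, o5$max_distance, tolerance = 1e-12)
  expect_equal(r5$mirv_max_dissimilarity, o5$max_dissimilarity,
               tolerance = 1e-12)

  # identical lesions: both scores collapse to zero
  M_same <- rbind(L1 = c(1, 2), L2 = c(1, 2), L3 = c(1, 2))
  r_same <- patient_mirv(M_same)
  expect_equal(r_same$mirv_max_distance, 0)
  expect_equal(r_same$mirv_max_dissimilarity, 0)

  expect_error(patient_mirv(M2[1, , drop = FALSE]), "fewer than 2")
})

test_that("argmax ties resolve to the lexicographically smallest lesion pair", {
  # unit square: the two diagonals tie exactly at sqrt(2)
  M <- rbind(Ld = c(2, 2), Lc = c(2, 1), Lb = c(1, 2), La = c(1, 1))
  r <- patient_mirv(M)
  expect_equal(r$argmax_pair_distance, c("La", "Ld"))
})

test_that("cohort scoring matches brute force and is permutation invariant", {
  set.seed(32)
  pid <- rep(c("P1", "P2", "P3"), times = c(2, 3, 4))
  lid <- unlist(lapply(c(2, 3, 4), function(k) paste0("L", seq_len(k))))
  M <- matrix(rnorm(9 * 5), 9, 5)
  res <- cohort_mirv(M, pid, lid, standardize = TRUE)
  Z <- standardize_features(M)
  for (p in unique(pid)) {
    o <- oracle_patient_mirv(Z[pid == p, , drop = FALSE])
    expect_equal(res$mirv_max_distance[res$patient_id == p],
                 o$max_distance, tolerance = 1e-10)
    expect_equal(res$mirv_max_dissimilarity[res$patient_id == p],
                 o$max_dissimilarity, tolerance = 1e-10)
  }

  set.seed(33)
  perm <- sample(9)
  res_p <- cohort_mirv(M[perm, ], pid[perm], lid[perm], standardize = TRUE)
  res_p <- res_p[match(res$patient_id, res_p$patient_id), ]
  expect_equal(res_p$mirv_max_distance, res$mirv_max_distance)
  expect_equal(res_p$argmax_distance_a, res$argmax_distance_a)

  # single-lesion patients are skipped with a warning in non-strict mode
  pid1 <- c(pid, "P4")
  M1 <- rbind(M, rnorm(5))
  expect_warning(res1 <- cohort_mirv(M1, pid1, c(lid, "L1")), "skipped")
  expect_false("P4" %in% res1$patient_id)
  expect_error(cohort_mirv(M1, pid1, c(lid, "L1"), strict = TRUE), "P4")
})

test_that("scores obey monotonicity, scale invariance and homogeneity", {
  set.seed(34)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    M <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(paste0("L", seq_len(n)), NULL))
    r <- patient_mirv(M)
    # appending a lesion never decreases either maximum
    M_plus <- rbind(M, Lx = rnorm(4))
    r_plus <- patient_mirv(M_plus)
    expect_gte(r_plus$mirv_max_distance, r$mirv_max_distance)
    expect_gte(r_plus$mirv_max_dissimilarity, r$mirv_max_dissimilarity)
    # positive scaling of one lesion leaves dissimilarity unchanged
    M_s <- M
    M_s[1, ] <- M_s[1, ] * 7.3
    expect_equal(patient_mirv(M_s)$mirv_max_dissimilarity,
                 r$mirv_max_dissimilarity, tolerance = 1e-12)
    # global scaling: distance homogeneous of degree 1, dissimilarity fixed
    r_c <- patient_mirv(M * 2.5)
    expect_equal(r_c$mirv_max_distance, 2.5 * r$mirv_max_distance,
                 tolerance = 1e-12)
    expect_equal(r_c$mirv_max_dissimilarity, r$mirv_max_dissimilarity,
                 tolerance = 1e-12)
  }
})
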