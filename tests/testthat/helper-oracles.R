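# Independent oracles used across the suite. Each recomputes a quantity by
# the most direct route available (double loops, closed formulas, grid
# maximization) so the vectorized implementations are checked against code
# that shares nothing with them.

# Exhaustive double-loop maxima over all lesion pairs.
oracle_patient_mirv <- function(M) {
  n <- nrow(M)
  best_d <- -Inf
  best_c <- -Inf
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      u <- M[i, ]
      v <- M[j, ]
      d <- sqrt(sum((u - v)^2))
      cd <- 1 - sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
      if (d > best_d) best_d <- d
      if (cd > best_c) best_c <- cd
    }
  }
  list(max_distance = best_d, max_dissimilarity = best_c)
}

# Rank correlation as Pearson correlation of average ranks.
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Step-up BH by the written formula q_(i) = min_{j >= i} m p_(j) / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  q
}

# Cox partial log-likelihood (no ties) maximized over the coefficient.
oracle_cox_coef <- function(time, event, x, interval = c(-20, 20)) {
  nll <- function(b) {
    ll <- 0
    for (i in seq_along(time)) {
      if (event[i] == 1) {
        risk <- time >= time[i]
        ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
      }
    }
    -ll
  }
  stats::optimize(nll, interval, tol = 1e-9)$minimum
}

# Two-group log-rank chi-square from observed-minus-expected over
# hypergeometric variance at each distinct event time.
oracle_logrank_chisq <- function(time, event, group) {
  g <- as.integer(factor(group))
  stopifnot(max(g) == 2)
  O1 <- 0; E1 <- 0; V <- 0
  for (s in sort(unique(time[event == 1]))) {
    at_risk <- time >= s
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == s & event == 1)
    d1 <- sum(time == s & event == 1 & g == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# Random lesion-by-feature matrix seeded with the nuisance structure the
# reduction pipeline is built to remove: a near-constant column, two
# monotone volume proxies and a duplicated column among clean features.
make_noisy_matrix <- function(seed, n = 400, n_clean = 6) {
  set.seed(seed)
  volumes <- rlnorm(n, 8.5, 1)
  clean <- sapply(seq_len(n_clean), function(j) rnorm(n, 0, 2^j))
  colnames(clean) <- sprintf("clean_%02d", seq_len(n_clean))
  M <- cbind(clean,
             dup_clean_01 = clean[, 1],
             vol_log = log(volumes),
             vol_sq = volumes^2,
             near_const = 1 + rnorm(n, 0, 1e-7))
  list(M = M, volumes = volumes)
}

# Small two-patient lesion table written to a temp CSV.
write_toy_lesion_csv <- function(path, drop_col = NULL, na_cell = FALSE) {
  df <- data.frame(
    patient_id = c("P1", "P1", "P2", "P2"),
    lesion_id = c("L1", "L2", "L1", "L2"),
    baseline_volume_mm3 = c(100, 200, 150, 250),
    followup_volume_mm3 = c(50, 210, 90, 260),
    featA = c(1.5, 2.5, 3.5, 4.5),
    featB = c(0.1, 0.2, 0.3, 0.4),
    featC = c(10, 20, 30, 40))
  if (na_cell) df$featB[2] <- NA
  if (!is.null(drop_col)) df[[drop_col]] <- NULL
  write.csv(df, path, row.names = FALSE)
  path
}

write_toy_clinical_csv <- function(path, recist_bad = FALSE,
                                   os_zero = FALSE, ctdna = FALSE) {
  df <- data.frame(
    patient_id = c("P1", "P2"),
    os_time = c(1.2, 2.5),
    os_event = c(1, 0),
    histology = c("Leiomyosarcoma", "Other"),
    age = c(60, 55),
    performance_status = c(0, 1),
    recist = c("SD", "PD"))
  if (recist_bad) df$recist[1] <- "XX"
  if (os_zero) df$os_time[1] <- 0
  if (ctdna) {
    df$ctdna_pre <- c(0, 1)
    df$ctdna_post <- c(1, 1)
  }
  write.csv(df, path, row.names = FALSE)
  path
}
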