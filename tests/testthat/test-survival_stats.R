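make_surv_df <- function(time, event, x) {
  data.frame(os_time = time, os_event = event, x = x)
}

test_that("Cox fits match the partial-likelihood oracle and respect symmetry", {
  # identical event-time patterns in the two groups: coefficient 0
  d_sym <- make_surv_df(c(1, 2, 3, 1, 2, 3), rep(1, 6),
                        c(0, 0, 0, 1, 1, 1))
  fit_sym <- fit_cox(d_sym, mirv_var = "x", covariates = character(0),
                     interaction = NULL)
  expect_equal(fit_sym$table$coef[1], 0, tolerance = 1e-8)

  # n = 6, binary covariate, distinct times: brute-force maximization
  d6 <- make_surv_df(c(1.1, 2.3, 3.1, 4.7, 5.2, 6.9),
                     c(1, 1, 0, 1, 1, 1), c(1, 0, 1, 1, 0, 0))
  fit6 <- fit_cox(d6, mirv_var = "x", covariates = character(0),
                  interaction = NULL)
  oracle <- oracle_cox_coef(d6$os_time, d6$os_event, d6$x)
  expect_equal(fit6$table$coef[1], oracle, tolerance = 1e-4)
  expect_equal(fit6$table$hr[1], exp(fit6$table$coef[1]))
  expect_true(fit6$table$ci_lo[1] <= fit6$table$ci_hi[1])

  # simulated exponential survival with true HR = 2 is recovered
  set.seed(61)
  n <- 500
  x <- rbinom(n, 1, 0.5)
  t_true <- rexp(n, 0.2 * exp(log(2) * x))
  cens <- rexp(n, 0.05)
  d_sim <- make_surv_df(pmin(t_true, cens), as.numeric(t_true <= cens), x)
  fit_sim <- fit_cox(d_sim, mirv_var = "x", covariates = character(0),
                     interaction = NULL)
  expect_lt(fit_sim$table$ci_lo[1], 2)
  expect_gt(fit_sim$table$ci_hi[1], 2)
  expect_gt(fit_sim$table$coef[1], 0)

  # degenerate inputs are diagnostic errors
  expect_error(fit_cox(make_surv_df(1:4, rep(0, 4), c(0, 1, 0, 1)),
                       mirv_var = "x", covariates = character(0),
                       interaction = NULL), "no events")
  d_const <- make_surv_df(1:4, c(1, 1, 0, 1), rep(2, 4))
  expect_error(fit_cox(d_const, mirv_var = "x", covariates = character(0),
                       interaction = NULL), "constant")
})

test_that("median dichotomization sends ties to the low group", {
  g <- dichotomize(c(1, 2, 3, 4))
  expect_equal(as.character(g), c("low", "low", "high", "high"))
  expect_equal(attr(g, "cutpoint"), 2.5)
  g2 <- dichotomize(c(1, 1, 2))
  expect_equal(as.character(g2), c("low", "low", "high"))
  expect_error(dichotomize(rep(3, 5)), "constant")
})

test_that("log-rank matches the O-E/V oracle and Kaplan-Meier invariants hold", {
  # identical groups: statistic 0, p = 1
  t0 <- c(1, 2, 3, 1, 2, 3)
  e0 <- c(1, 0, 1, 1, 0, 1)
  g0 <- rep(c("a", "b"), each = 3)
  lr0 <- km_logrank(t0, e0, g0)
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-12)

  # 6-subject example with distinct event times against the hand formula
  t6 <- c(1, 3, 5, 2, 4, 6)
  e6 <- c(1, 1, 1, 1, 1, 0)
  g6 <- rep(c("a", "b"), each = 3)
  lr6 <- km_logrank(t6, e6, g6)
  expect_equal(lr6$chisq, oracle_logrank_chisq(t6, e6, g6),
               tolerance = 1e-10)
  expect_equal(lr6$p, pchisq(lr6$chisq, 1, lower.tail = FALSE))

  # KM curves start at 1, never increase, and exhaust the risk set
  curves_a <- lr6$curves[lr6$curves$group == "a", ]
  expect_equal(curves_a$surv[curves_a$time == 0], 1)
  expect_true(all(diff(curves_a$surv) <= 0))
  last <- curves_a[nrow(curves_a), ]
  expect_equal(last$n_risk - last$n_event,
               3 - sum(t6[g6 == "a"] < last$time) - last$n_event)

  # well-separated exponential arms are detected
  set.seed(62)
  ta <- rexp(100, 1)
  tb <- rexp(100, 3)
  lr_sep <- km_logrank(c(ta, tb), rep(1, 200),
                       rep(c("a", "b"), each = 100))
  expect_lt(lr_sep$p, 0.001)

  expect_error(km_logrank(t6, e6, rep("a", 6)), "2 non-empty groups")
})

test_that("subgroup analysis localizes a stratum-specific heterogeneity effect", {
  set.seed(63)
  n <- 240
  hist_lab <- sample(c("Leiomyosarcoma", "Other"), n, replace = TRUE)
  mirv_score <- runif(n, 0.1, 2)
  # hazard rises with the score only in the leiomyosarcoma stratum
  rate <- 0.4 * exp(1.2 * mirv_score * (hist_lab == "Leiomyosarcoma"))
  t_true <- rexp(n, rate)
  cens <- rexp(n, 0.1)
  d <- data.frame(os_time = pmin(t_true, cens),
                  os_event = as.numeric(t_true <= cens),
                  histology = hist_lab, mirv_max_dissimilarity = mirv_score)
  sg <- subgroup_analysis(d, min_size = 20)
  tab <- sg$table
  expect_lt(tab$p[tab$stratum == "Leiomyosarcoma"], 0.05)
  expect_gt(tab$p[tab$stratum == "Other"], 0.05)

  # a stratum below the size floor is skipped with a warning
  d_small <- d
  d_small$histology[1:3] <- "UPS"
  d_small$histology[-(1:3)] <- "Other"
  expect_warning(sg_small <- subgroup_analysis(d_small, min_size = 20),
                 "skipped")
  expect_true(sg_small$table$skipped[sg_small$table$stratum == "UPS"])

  # a single-level stratifier reduces to the full-cohort analysis
  d_one <- d
  d_one$histology <- "Other"
  sg_one <- subgroup_analysis(d_one, min_size = 20)
  expect_equal(nrow(sg_one$table), 1)
  full <- km_logrank(d$os_time, d$os_event,
                     dichotomize(d$mirv_max_dissimilarity))
  expect_equal(sg_one$table$chisq, full$chisq)
})
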