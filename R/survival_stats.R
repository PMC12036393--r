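# Survival analysis: multivariable Cox proportional hazards with an
# optional heterogeneity-by-histology interaction, median dichotomization,
# and Kaplan-Meier / log-rank subgroup comparisons.

#' Merge heterogeneity scores into the clinical table
#'
#' Inner join on `patient_id`; optionally pulls the baseline-volume total
#' (tumor burden covariate) from a response table.
#'
#' @param mirv Table from [cohort_mirv()].
#' @param clinical Clinical table.
#' @param response Optional response table supplying `baseline_total`.
#' @return Merged `data.frame`.
#' @export
survival_data <- function(mirv, clinical, response = NULL) {
  d <- merge(clinical, mirv[, c("patient_id", "mirv_max_distance",
                                "mirv_max_dissimilarity", "n_lesions")],
             by = "patient_id")
  if (!is.null(response)) {
    d <- merge(d, response[, c("patient_id", "baseline_total")],
               by = "patient_id", all.x = TRUE)
  }
  if (nrow(d) == 0) stop("no patients shared between tables", call. = FALSE)
  d[order(d$patient_id), , drop = FALSE]
}

#' Multivariable Cox proportional hazards model
#'
#' Fits overall survival on a continuous heterogeneity score plus clinical
#' covariates, with an optional score-by-subtype interaction. Ties are
#' handled with Efron's method. Categorical covariates are reference-coded;
#' default references are histology = `"Other"` and RECIST = `"SD"`.
#' Non-convergence or coefficient divergence (separation) raises a
#' diagnostic error rather than returning a silently unstable fit.
#'
#' @param data Merged table from [survival_data()].
#' @param mirv_var Continuous score column, e.g. `"mirv_max_dissimilarity"`.
#' @param covariates Adjustment covariate columns (default: histology, age,
#'   performance status, RECIST; `baseline_total` is added when present).
#' @param interaction Optional covariate interacted with the score
#'   (e.g. `"histology"`), or `NULL`.
#' @param ref Named list of reference levels for categorical covariates.
#' @param time_var,event_var Survival time / event indicator columns.
#' @return A `mirv_cox` object: list with `table` (term, coef, hr, ci_lo,
#'   ci_hi, se, p), `loglik`, `n`, `events`, `formula` and the underlying
#'   [survival::coxph()] fit.
#' @export
fit_cox <- function(data, mirv_var = "mirv_max_dissimilarity",
                    covariates = NULL, interaction = NULL,
                    ref = list(histology = "Other", recist = "SD"),
                    time_var = "os_time", event_var = "os_event") {
  if (is.null(covariates)) {
    covariates <- intersect(c("histology", "age", "performance_status",
                              "recist", "baseline_total"), colnames(data))
  }
  needed <- c(time_var, event_var, mirv_var, covariates, interaction)
  missing_cols <- setdiff(needed, colnames(data))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (sum(data[[event_var]]) < 1) stop("no events in data", call. = FALSE)

  d <- data
  for (v in unique(c(covariates, interaction))) {
    if (is.character(d[[v]])) {
      lev <- unique(d[[v]])
      if (!is.null(ref[[v]]) && ref[[v]] %in% lev) {
        lev <- c(ref[[v]], setdiff(sort(lev), ref[[v]]))
      } else {
        lev <- sort(lev)
      }
      d[[v]] <- factor(d[[v]], levels = lev)
    }
  }
  for (v in c(mirv_var, covariates)) {
    if (length(unique(d[[v]])) < 2) {
      stop("covariate '", v, "' is constant", call. = FALSE)
    }
  }

  rhs <- c(mirv_var, covariates)
  if (!is.null(interaction)) {
    rhs <- c(rhs, paste0(mirv_var, ":", interaction))
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time_var, ", ", event_var, ") ~ ",
    paste(rhs, collapse = " + ")))

  diverged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d, ties = "efron", model = TRUE),
    warning = function(w) {
      if (grepl("infinite|did not converge|out of iterations",
                conditionMessage(w), ignore.case = TRUE)) {
        diverged <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  if (diverged || any(is.na(stats::coef(fit)))) {
    stop("Cox model did not converge (possible separation); ",
         "inspect covariates or reduce the model", call. = FALSE)
  }
  s <- summary(fit)
  tab <- data.frame(
    term = rownames(s$coefficients),
    coef = s$coefficients[, "coef"],
    hr = s$coefficients[, "exp(coef)"],
    ci_lo = s$conf.int[, "lower .95"],
    ci_hi = s$conf.int[, "upper .95"],
    se = s$coefficients[, "se(coef)"],
    p = s$coefficients[, "Pr(>|z|)"],
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, loglik = fit$loglik[2], n = s$n,
                 events = s$nevent, formula = deparse(fml), fit = fit),
            class = "mirv_cox")
}

#' @export
print.mirv_cox <- function(x, ...) {
  cat("Cox proportional hazards (Efron ties): n =", x$n,
      ", events =", x$events, "\n")
  tab <- x$table
  tab$hr <- signif(tab$hr, 3)
  tab$p <- signif(tab$p, 3)
  print(tab[, c("term", "coef", "hr", "ci_lo", "ci_hi", "p")], digits = 3)
  invisible(x)
}

#' Dichotomize a continuous score at the median
#'
#' Values at or below the median go to `"low"`, above to `"high"`; the
#' cutpoint and method are recorded as attributes for the run manifest.
#'
#' @param values Numeric vector with >= 2 distinct values.
#' @param method Only `"median"` is implemented.
#' @return Factor with levels `low`, `high`; attributes `cutpoint`,
#'   `method`.
#' @export
dichotomize <- function(values, method = "median") {
  method <- match.arg(method, "median")
  if (length(unique(values)) < 2) {
    stop("cannot dichotomize a constant input", call. = FALSE)
  }
  cut <- stats::median(values)
  g <- factor(ifelse(values <= cut, "low", "high"), levels = c("low", "high"))
  attr(g, "cutpoint") <- cut
  attr(g, "method") <- method
  g
}

#' Kaplan-Meier curves and the log-rank test
#'
#' Product-limit survival estimates per group plus the log-rank statistic
#' (observed-minus-expected over hypergeometric variance at each distinct
#' event time).
#'
#' @param time Follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @param group Group labels (factor or coercible); every group must be
#'   non-empty.
#' @return A `mirv_logrank` object: `chisq`, `df`, `p`, `n` (group sizes),
#'   `obs`, `exp`, and `curves` (group, time, n_risk, n_event, surv, with a
#'   time-0 row at survival 1 per group).
#' @export
km_logrank <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2) {
    stop("need at least 2 non-empty groups", call. = FALSE)
  }
  if (any(table(group) < 1)) stop("empty group", call. = FALSE)

  sf <- survival::survfit(survival::Surv(time, event) ~ group)
  strata_names <- sub("^group=", "", rep(names(sf$strata), sf$strata))
  curves <- data.frame(group = strata_names, time = sf$time,
                       n_risk = sf$n.risk, n_event = sf$n.event,
                       surv = sf$surv, stringsAsFactors = FALSE)
  zero <- data.frame(group = levels(group), time = 0,
                     n_risk = as.vector(table(group)), n_event = 0, surv = 1,
                     stringsAsFactors = FALSE)
  curves <- rbind(zero, curves)
  curves <- curves[order(curves$group, curves$time), , drop = FALSE]
  rownames(curves) <- NULL

  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1
  p <- stats::pchisq(sd$chisq, df = df, lower.tail = FALSE)
  structure(list(chisq = unname(sd$chisq), df = df, p = p,
                 n = as.vector(table(group)), obs = as.vector(sd$obs),
                 exp = as.vector(sd$exp), curves = curves),
            class = "mirv_logrank")
}

#' @export
print.mirv_logrank <- function(x, ...) {
  cat("Log-rank test: chisq =", signif(x$chisq, 4), "on", x$df,
      "df, p =", signif(x$p, 3), "\n")
  cat("  group sizes:", paste(x$n, collapse = ", "), "\n")
  invisible(x)
}

#' Subgroup survival analysis with score dichotomization
#'
#' Within each level of a stratifying covariate (default histology), splits
#' patients at the within-stratum median of the heterogeneity score and
#' compares overall survival between the low and high groups with a
#' log-rank test. Strata below the minimum size, or with a constant score,
#' are skipped with a warning. The per-stratum p-values are exploratory and
#' unadjusted for the number of strata; interpret with a multiplicity
#' caveat.
#'
#' @param data Merged table from [survival_data()].
#' @param mirv_var Continuous score column to dichotomize.
#' @param stratify_by Stratifying column (default `"histology"`).
#' @param min_size Minimum stratum size (default 20).
#' @param time_var,event_var Survival columns.
#' @return A `mirv_subgroups` object: `table` (stratum, n, events,
#'   cutpoint, chisq, p, skipped) and `results` (named list of
#'   `mirv_logrank` objects for analyzed strata).
#' @export
subgroup_analysis <- function(data, mirv_var = "mirv_max_dissimilarity",
                              stratify_by = "histology", min_size = 20,
                              time_var = "os_time", event_var = "os_event") {
  levels_ <- unique(data[[stratify_by]])
  results <- list()
  rows <- lapply(levels_, function(lv) {
    sub <- data[data[[stratify_by]] == lv, , drop = FALSE]
    n <- nrow(sub)
    base <- data.frame(stratum = lv, n = n,
                       events = sum(sub[[event_var]]),
                       cutpoint = NA_real_, chisq = NA_real_, p = NA_real_,
                       skipped = TRUE, stringsAsFactors = FALSE)
    if (n < min_size) {
      warning("stratum '", lv, "' has ", n, " < ", min_size,
              " patients; skipped", call. = FALSE)
      return(base)
    }
    g <- tryCatch(dichotomize(sub[[mirv_var]]),
                  error = function(e) NULL)
    if (is.null(g) || nlevels(droplevels(g)) < 2) {
      warning("stratum '", lv, "' has a degenerate score split; skipped",
              call. = FALSE)
      return(base)
    }
    lr <- km_logrank(sub[[time_var]], sub[[event_var]], g)
    results[[lv]] <<- lr
    base$cutpoint <- attr(g, "cutpoint")
    base$chisq <- lr$chisq
    base$p <- lr$p
    base$skipped <- FALSE
    base
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, results = results,
                 mirv_var = mirv_var, stratify_by = stratify_by),
            class = "mirv_subgroups")
}

#' @export
print.mirv_subgroups <- function(x, ...) {
  cat("Subgroup log-rank analysis of", x$mirv_var, "by", x$stratify_by,
      "(median split; unadjusted p-values)\n")
  print(x$table, digits = 3)
  invisible(x)
}
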