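# Stepwise radiomic feature reduction: variance filter, volume-surrogate
# filter, pairwise-redundancy filter — applied in that order. Thresholds are
# strict inequalities: variance strictly below the median is removed,
# |Spearman rho| strictly above the cutoffs is removed.

spearman_rho <- function(x, y) {
  suppressWarnings(stats::cor(x, y, method = "spearman"))
}

#' Remove low-variance features
#'
#' Drops every feature whose sample variance falls strictly below the median
#' variance across all features of the input matrix; features sitting exactly
#' at the median are retained. The median is recomputed on each call.
#'
#' @param M Numeric lesion-by-feature matrix with named columns.
#' @return List with `matrix` (retained columns), `removed` (character),
#'   `variances` (named numeric) and `median_variance`.
#' @export
variance_filter <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) < 2) stop("variance undefined for fewer than 2 lesions", call. = FALSE)
  v <- apply(M, 2, stats::var)
  med <- stats::median(v)
  removed <- colnames(M)[v < med]
  list(matrix = M[, v >= med, drop = FALSE], removed = removed,
       variances = v, median_variance = med)
}

#' Remove volume-surrogate features
#'
#' Drops features whose absolute Spearman correlation with baseline tumor
#' volume exceeds `tau` (default 0.1). Correlations are pooled over all
#' lesions of all patients. A feature whose correlation is undefined
#' (constant column) is retained, since no volume link can be established.
#'
#' @param M Numeric lesion-by-feature matrix.
#' @param volumes Baseline volume (mm^3) per row of `M`.
#' @param tau Absolute-correlation cutoff in `[0, 1]`.
#' @return List with `matrix`, `removed` and `rho` (named correlations).
#' @export
volume_filter <- function(M, volumes, tau = 0.1) {
  M <- as.matrix(M)
  if (!is.numeric(tau) || length(tau) != 1 || tau < 0 || tau > 1) {
    stop("'tau' must lie in [0, 1]", call. = FALSE)
  }
  if (length(volumes) != nrow(M)) {
    stop("'volumes' must have one value per row of M", call. = FALSE)
  }
  if (nrow(M) < 3) stop("need at least 3 lesions for rank correlation", call. = FALSE)
  rho <- apply(M, 2, spearman_rho, y = volumes)
  drop <- !is.na(rho) & abs(rho) > tau
  list(matrix = M[, !drop, drop = FALSE], removed = colnames(M)[drop],
       rho = rho)
}

#' Remove mutually redundant features
#'
#' Greedy, order-deterministic redundancy pruning: features are scanned in
#' column order and feature j is dropped iff its absolute Spearman
#' correlation with some already-retained earlier feature exceeds `tau`
#' (default 0.7). The retained set therefore has all pairwise
#' `|rho| <= tau`, and earlier columns take priority — reorder columns to
#' change priority. Idempotent.
#'
#' @param M Numeric lesion-by-feature matrix.
#' @param tau Absolute-correlation cutoff.
#' @return List with `matrix`, `removed`, and `partner` (for each removed
#'   feature, the retained feature that triggered its removal).
#' @export
correlation_filter <- function(M, tau = 0.7) {
  M <- as.matrix(M)
  if (!is.numeric(tau) || length(tau) != 1 || tau < 0 || tau > 1) {
    stop("'tau' must lie in [0, 1]", call. = FALSE)
  }
  if (nrow(M) < 3) stop("need at least 3 lesions for rank correlation", call. = FALSE)
  p <- ncol(M)
  if (p <= 1) {
    return(list(matrix = M, removed = character(), partner = character()))
  }
  C <- suppressWarnings(stats::cor(M, method = "spearman"))
  keep <- logical(p)
  partner <- character()
  removed <- character()
  for (j in seq_len(p)) {
    r <- abs(C[j, keep])
    hit <- which(!is.na(r) & r > tau)
    if (length(hit)) {
      removed <- c(removed, colnames(M)[j])
      partner <- c(partner, colnames(M)[keep][hit[1]])
    } else {
      keep[j] <- TRUE
    }
  }
  list(matrix = M[, keep, drop = FALSE], removed = removed, partner = partner)
}

#' Stepwise feature reduction pipeline
#'
#' Applies, in order: (1) the variance filter (drop variance strictly below
#' the median), (2) the volume filter (drop `|rho| > vol_tau` against
#' baseline volume), (3) the pairwise redundancy filter (greedy drop at
#' `|rho| > corr_tau`). The surviving feature set is the one on which the
#' heterogeneity metrics are computed.
#'
#' @param M Numeric lesion-by-feature matrix with named columns.
#' @param volumes Baseline volume (mm^3) per row.
#' @param vol_tau Volume-correlation cutoff (default 0.1).
#' @param corr_tau Pairwise-correlation cutoff (default 0.7).
#' @return List with `matrix` (the reduced matrix) and `report`, a
#'   `mirv_reduction_report`: per stage, a data.frame of removed features and
#'   the statistic that triggered removal.
#' @export
reduce_features <- function(M, volumes, vol_tau = 0.1, corr_tau = 0.7) {
  M <- as.matrix(M)
  input_features <- colnames(M)

  s1 <- variance_filter(M)
  stage_var <- data.frame(feature = s1$removed,
                          statistic = unname(s1$variances[s1$removed]),
                          stringsAsFactors = FALSE)

  s2 <- volume_filter(s1$matrix, volumes, tau = vol_tau)
  stage_vol <- data.frame(feature = s2$removed,
                          statistic = unname(s2$rho[s2$removed]),
                          stringsAsFactors = FALSE)

  s3 <- correlation_filter(s2$matrix, tau = corr_tau)
  stage_cor <- data.frame(feature = s3$removed,
                          partner = s3$partner,
                          stringsAsFactors = FALSE)

  if (ncol(s3$matrix) == 0) {
    stop("empty feature set: all features were removed by the reduction pipeline",
         call. = FALSE)
  }
  report <- structure(list(
    variance = stage_var, volume = stage_vol, correlation = stage_cor,
    median_variance = s1$median_variance,
    vol_tau = vol_tau, corr_tau = corr_tau,
    n_input = length(input_features), n_retained = ncol(s3$matrix),
    retained = colnames(s3$matrix)
  ), class = "mirv_reduction_report")
  list(matrix = s3$matrix, report = report)
}

#' @export
print.mirv_reduction_report <- function(x, ...) {
  cat("Feature reduction:", x$n_input, "->", x$n_retained, "features\n")
  cat("  variance filter   (< median ", signif(x$median_variance, 4), "): ",
      nrow(x$variance), " removed\n", sep = "")
  cat("  volume filter     (|rho| > ", x$vol_tau, "): ",
      nrow(x$volume), " removed\n", sep = "")
  cat("  redundancy filter (|rho| > ", x$corr_tau, "): ",
      nrow(x$correlation), " removed\n", sep = "")
  invisible(x)
}
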