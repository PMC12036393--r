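# Rank-correlation association analysis: pairwise Spearman correlations
# among heterogeneity scores, response metrics, baseline-volume controls and
# ctDNA labels, with Benjamini-Hochberg FDR control per matrix.

#' Spearman rank correlation with a large-sample p-value
#'
#' Average-rank ties; the two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom,
#' with `p = 0` at `|rho| = 1`. Pairs with a missing value in either input
#' are dropped. A constant input leaves the correlation undefined: the
#' result carries `ok = FALSE` and is excluded from any FDR family.
#'
#' @param x,y Numeric vectors of equal length with >= 3 complete pairs.
#' @return List with `rho`, `p`, `n` (complete pairs) and `ok`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("inputs differ in length", call. = FALSE)
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  rho <- suppressWarnings(stats::cor(x, y, method = "spearman"))
  if (is.na(rho)) {
    return(list(rho = NA_real_, p = NA_real_, n = n, ok = FALSE))
  }
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n, ok = TRUE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted values `q_(i) = min_(j >= i) m * p_(j) / j`, returned in
#' the input order. Missing entries stay missing and do not count toward the
#' family size.
#'
#' @param pvals Numeric p-values in `[0, 1]` (NA allowed).
#' @return Adjusted q-values, same length and order.
#' @export
fdr_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Pairwise association matrix with FDR control
#'
#' Tests every unordered pair of the supplied variables with
#' [spearman_cor()] and adjusts the resulting p-values as one
#' Benjamini-Hochberg family (the diagonal is excluded; pairs with an
#' undefined correlation are excluded from the family). Cells whose q-value
#' exceeds `alpha` are flagged `displayed = FALSE`, mirroring the convention
#' of blanking non-significant cells in a correlation heat matrix.
#'
#' @param data A data.frame of numeric columns (binary variables coded 0/1
#'   enter as ordinary ranks).
#' @param variables Columns to test; defaults to all numeric columns.
#' @param alpha Display cutoff on the FDR-adjusted value (default 0.05).
#' @param min_n Minimum complete pairs per cell (default 3; fewer is an
#'   error).
#' @return A `data.frame` with one row per unordered pair: `var1`, `var2`,
#'   `rho`, `p`, `q`, `n`, `displayed`.
#' @export
association_matrix <- function(data, variables = NULL, alpha = 0.05,
                               min_n = 3) {
  if (is.null(variables)) {
    variables <- colnames(data)[vapply(data, is.numeric, logical(1))]
  }
  missing_vars <- setdiff(variables, colnames(data))
  if (length(missing_vars)) {
    stop("variable(s) not in data: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  if (length(variables) < 2) {
    stop("need at least 2 variables to build an association matrix",
         call. = FALSE)
  }
  pairs <- utils::combn(variables, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    cc <- sum(stats::complete.cases(data[[a]], data[[b]]))
    if (cc < min_n) {
      stop("fewer than ", min_n, " complete pairs for (", a, ", ", b, ")",
           call. = FALSE)
    }
    r <- spearman_cor(data[[a]], data[[b]])
    data.frame(var1 = a, var2 = b, rho = r$rho, p = r$p, n = r$n,
               ok = r$ok, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  out$q[out$ok] <- fdr_adjust(out$p[out$ok])
  out$displayed <- !is.na(out$q) & out$q <= alpha
  out$ok <- NULL
  out[, c("var1", "var2", "rho", "p", "q", "n", "displayed")]
}

#' Assemble the variables for an association analysis
#'
#' Joins the heterogeneity, response and clinical tables on `patient_id` and
#' selects the variable set for one of the two study subsets:
#'
#' * `"volumetric"`: both heterogeneity scores, the response range, the TSRC
#'   label, and the three baseline-volume controls.
#' * `"liquid_biopsy"`: both heterogeneity scores, pre- and post-treatment
#'   ctDNA positivity, and the baseline-volume controls.
#'
#' Patients missing from a required table are dropped (they fall outside
#' that subset).
#'
#' @param mirv Cohort heterogeneity table from [cohort_mirv()].
#' @param response Response table from [cohort_response()]; required for
#'   both subsets (it carries the baseline-volume controls).
#' @param clinical Clinical table; required for `"liquid_biopsy"`.
#' @param subset `"volumetric"` or `"liquid_biopsy"`.
#' @return A `data.frame` of numeric variables keyed by `patient_id`.
#' @export
association_data <- function(mirv, response, clinical = NULL,
                             subset = c("volumetric", "liquid_biopsy")) {
  subset <- match.arg(subset)
  d <- merge(mirv[, c("patient_id", "mirv_max_distance",
                      "mirv_max_dissimilarity")],
             response[, c("patient_id", "response_range", "tsrc",
                          "baseline_range", "baseline_sd", "baseline_total")],
             by = "patient_id")
  if (subset == "liquid_biopsy") {
    if (is.null(clinical) || !all(c("ctdna_pre", "ctdna_post") %in%
                                    colnames(clinical))) {
      stop("liquid-biopsy subset requires a clinical table with ",
           "'ctdna_pre' and 'ctdna_post'", call. = FALSE)
    }
    d <- merge(d, clinical[, c("patient_id", "ctdna_pre", "ctdna_post")],
               by = "patient_id")
    d <- d[, c("patient_id", "mirv_max_distance", "mirv_max_dissimilarity",
               "ctdna_pre", "ctdna_post", "baseline_range", "baseline_sd",
               "baseline_total")]
  } else {
    d <- d[, c("patient_id", "mirv_max_distance", "mirv_max_dissimilarity",
               "response_range", "tsrc", "baseline_range", "baseline_sd",
               "baseline_total")]
  }
  if (nrow(d) == 0) stop("no patients qualify for subset '", subset, "'",
                         call. = FALSE)
  d[order(d$patient_id), , drop = FALSE]
}
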