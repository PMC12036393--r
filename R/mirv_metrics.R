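# Per-patient intertumor heterogeneity scores: the maximum pairwise
# Euclidean distance and maximum pairwise cosine dissimilarity between
# lesion radiomic feature vectors, evaluated over all C(n,2) lesion pairs.

#' Z-score feature columns cohort-wide
#'
#' Rescales each feature to mean 0 and sample standard deviation 1 over all
#' lesions in the matrix. Radiomic features span wildly different scales;
#' without this, a single large-scale feature dominates the Euclidean
#' metric.
#'
#' @param M Numeric lesion-by-feature matrix (>= 2 rows).
#' @return Standardized matrix of the same shape.
#' @export
standardize_features <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) < 2) stop("need at least 2 lesions to standardize", call. = FALSE)
  sds <- apply(M, 2, stats::sd)
  zero <- sds == 0
  if (any(zero)) {
    stop("zero-variance column(s): ",
         paste(colnames(M)[zero], collapse = ", "), call. = FALSE)
  }
  out <- sweep(sweep(M, 2, colMeans(M), "-"), 2, sds, "/")
  attr(out, "patient_id") <- attr(M, "patient_id")
  out
}

#' Euclidean distance between two feature vectors
#'
#' @param u,v Numeric vectors of equal length.
#' @return `sqrt(sum((u - v)^2))`.
#' @export
euclidean_distance <- function(u, v) {
  if (length(u) != length(v)) stop("vectors differ in length", call. = FALSE)
  if (length(u) < 1) stop("vectors must be non-empty", call. = FALSE)
  sqrt(sum((u - v)^2))
}

#' Cosine dissimilarity between two feature vectors
#'
#' One minus the cosine of the angle between `u` and `v`; 0 for parallel
#' vectors, 1 for orthogonal, 2 for antipodal. Invariant to positive
#' rescaling of either argument; undefined (error) for a zero vector.
#'
#' @param u,v Numeric vectors of equal length with nonzero norm.
#' @return Value in `[0, 2]`.
#' @export
cosine_dissimilarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors differ in length", call. = FALSE)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("cosine dissimilarity undefined for a zero-norm vector", call. = FALSE)
  }
  d <- 1 - sum(u * v) / (nu * nv)
  min(max(d, 0), 2)
}

# Argmax over the upper triangle of a symmetric pair matrix; ties broken by
# the lexicographically smallest (sorted) lesion-id pair.
.pick_max_pair <- function(V, ids) {
  ut <- which(upper.tri(V), arr.ind = TRUE)
  vals <- V[ut]
  m <- max(vals)
  cand <- ut[vals == m, , drop = FALSE]
  a <- pmin(ids[cand[, 1]], ids[cand[, 2]])
  b <- pmax(ids[cand[, 1]], ids[cand[, 2]])
  k <- order(a, b)[1]
  list(value = m, pair = c(a[k], b[k]))
}

#' Heterogeneity score for one patient
#'
#' Evaluates Euclidean distance and cosine dissimilarity over all unordered
#' lesion pairs and returns the maximum of each with the arg-max pair (the
#' most divergent tumor pair). Ties are broken by the lexicographically
#' smallest lesion-id pair.
#'
#' @param M Numeric matrix of lesion feature vectors, one row per lesion
#'   (>= 2 rows), typically already reduced and standardized.
#' @param lesion_id Lesion identifiers; defaults to `rownames(M)`.
#' @return List with `mirv_max_distance`, `mirv_max_dissimilarity`,
#'   `n_lesions`, `argmax_pair_distance`, `argmax_pair_dissimilarity`.
#' @export
patient_mirv <- function(M, lesion_id = rownames(M)) {
  M <- as.matrix(M)
  if (nrow(M) < 2) {
    stop("heterogeneity score undefined for fewer than 2 lesions", call. = FALSE)
  }
  if (is.null(lesion_id)) lesion_id <- as.character(seq_len(nrow(M)))
  if (anyDuplicated(lesion_id)) stop("lesion ids must be unique", call. = FALSE)

  D <- as.matrix(stats::dist(M))
  norms <- sqrt(rowSums(M^2))
  if (any(norms == 0)) {
    stop("zero-norm lesion vector(s): ",
         paste(lesion_id[norms == 0], collapse = ", "), call. = FALSE)
  }
  S <- tcrossprod(M) / outer(norms, norms)
  DS <- pmin(pmax(1 - S, 0), 2)

  best_d <- .pick_max_pair(D, lesion_id)
  best_c <- .pick_max_pair(DS, lesion_id)
  list(mirv_max_distance = best_d$value,
       mirv_max_dissimilarity = best_c$value,
       n_lesions = nrow(M),
       argmax_pair_distance = best_d$pair,
       argmax_pair_dissimilarity = best_c$pair,
       mean_distance = mean(D[upper.tri(D)]),
       mean_dissimilarity = mean(DS[upper.tri(DS)]))
}

#' Heterogeneity scores for a cohort
#'
#' Computes [patient_mirv()] for every patient with at least 2 lesions.
#' Features are z-scored cohort-wide first (default; disable with
#' `standardize = FALSE` for pre-scaled input). Single-lesion patients are
#' skipped with a warning, or raise an error in strict mode.
#'
#' @param M Reduced lesion-by-feature matrix, one row per lesion.
#' @param patient_id Patient id per row; defaults to the `patient_id`
#'   attribute left by [lesion_feature_matrix()].
#' @param lesion_id Lesion id per row; defaults to `rownames(M)`.
#' @param standardize Z-score columns cohort-wide before scoring.
#' @param strict Error (rather than warn) on patients with fewer than
#'   2 lesions.
#' @param extras Also report mean pairwise distance/dissimilarity. These
#'   per-patient means are auxiliary summaries, not part of the max-based
#'   heterogeneity score.
#' @return A `data.frame`, one row per qualifying patient, in first-seen
#'   patient order.
#' @export
cohort_mirv <- function(M, patient_id = attr(M, "patient_id"),
                        lesion_id = rownames(M),
                        standardize = TRUE, strict = FALSE, extras = FALSE) {
  M <- as.matrix(M)
  if (is.null(patient_id) || length(patient_id) != nrow(M)) {
    stop("'patient_id' must have one value per row of M", call. = FALSE)
  }
  if (is.null(lesion_id)) lesion_id <- as.character(seq_len(nrow(M)))
  if (standardize) M <- standardize_features(M)

  counts <- table(patient_id)
  singletons <- names(counts)[counts < 2]
  if (length(singletons)) {
    msg <- paste0(length(singletons),
                  " patient(s) with < 2 lesions skipped: ",
                  paste(utils::head(singletons, 5), collapse = ", "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  pats <- unique(patient_id)
  pats <- pats[!pats %in% singletons]
  if (!length(pats)) {
    stop("no patient has >= 2 lesions; cohort heterogeneity undefined",
         call. = FALSE)
  }
  rows <- lapply(pats, function(p) {
    idx <- which(patient_id == p)
    r <- patient_mirv(M[idx, , drop = FALSE], lesion_id[idx])
    out <- data.frame(
      patient_id = p,
      mirv_max_distance = r$mirv_max_distance,
      mirv_max_dissimilarity = r$mirv_max_dissimilarity,
      n_lesions = r$n_lesions,
      argmax_distance_a = r$argmax_pair_distance[1],
      argmax_distance_b = r$argmax_pair_distance[2],
      argmax_dissimilarity_a = r$argmax_pair_dissimilarity[1],
      argmax_dissimilarity_b = r$argmax_pair_dissimilarity[2],
      stringsAsFactors = FALSE)
    if (extras) {
      out$mean_distance <- r$mean_distance
      out$mean_dissimilarity <- r$mean_dissimilarity
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
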