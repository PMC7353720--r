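#' Weighted-Z fixed-effect meta-analysis
#'
#' Combines per-pair Z-scores across cohorts with square-root-of-sample-size
#' weights (the METAL-style weighted Z):
#' `z_meta = sum(sqrt(n_k) z_k) / sqrt(sum(n_k))`, with a two-sided normal
#' p-value.
#'
#' @param z_by_cohort numeric matrix, pairs x cohorts (a vector is treated
#'   as one pair), or a vector for a single pair.
#' @param n_by_cohort sample sizes per cohort.
#' @return data.frame with `z_meta`, `p_meta`.
#' @export
weighted_z_meta <- function(z_by_cohort, n_by_cohort) {
  z <- if (is.matrix(z_by_cohort)) z_by_cohort else matrix(z_by_cohort, nrow = 1)
  if (ncol(z) != length(n_by_cohort)) stop_data("one sample size per cohort required")
  if (anyNA(z)) stop_data("missing Z for some pair/cohort; align pairs before meta-analysis")
  w <- sqrt(n_by_cohort)
  z_meta <- as.vector(z %*% w) / sqrt(sum(n_by_cohort))
  data.frame(z_meta = z_meta, p_meta = 2 * pnorm(-abs(z_meta)))
}

#' Cochran's Q heterogeneity test
#'
#' Fixed-effect heterogeneity of per-cohort effect estimates (here the
#' residual correlations) with known variances: inverse-variance weighted
#' mean `b`, `Q = sum((b_k - b)^2 / v_k)`, p-value from chi-squared with
#' K - 1 degrees of freedom.
#'
#' @param effects matrix pairs x cohorts (or vector for one pair) of
#'   residual correlations.
#' @param variances per-cohort variances (`sigma_hat^2`), length K >= 2.
#' @return data.frame with `q`, `q_p`.
#' @export
cochran_q <- function(effects, variances) {
  b <- if (is.matrix(effects)) effects else matrix(effects, nrow = 1)
  K <- length(variances)
  if (K < 2) stop_data("Cochran's Q needs >= 2 cohorts")
  if (ncol(b) != K) stop_data("one variance per cohort required")
  if (any(variances <= 0)) stop_data("variances must be positive")
  w <- 1 / variances
  bbar <- as.vector(b %*% w) / sum(w)
  q <- rowSums(sweep(b, 1, bbar, "-")^2 %*% diag(w, K))
  data.frame(q = q, q_p = pchisq(q, df = K - 1, lower.tail = FALSE))
}

#' Genomic-control inflation factor
#'
#' `lambda = median(z^2) / qchisq(0.5, 1)` (0.4549364...). Values at or
#' below 1 indicate no inflation of the test statistics.
#'
#' @param z Z-scores.
#' @return lambda.
#' @export
genomic_control_lambda <- function(z) {
  if (length(z) < 1) stop_data("need >= 1 Z value")
  median(z^2) / qchisq(0.5, df = 1)
}

#' Pairwise correlation of Z-scores between cohorts
#'
#' Shared fitness epistasis induces positive correlation between the
#' cohorts' Z-score vectors over the same bin pairs; under the null the
#' vectors are independent.
#'
#' @param z_by_cohort matrix pairs x cohorts with cohort column names.
#' @return data.frame with `cohort1`, `cohort2`, `r`.
#' @export
cohort_z_correlation <- function(z_by_cohort) {
  if (nrow(z_by_cohort) < 2) stop_data("need >= 2 shared pairs")
  cc <- cor(z_by_cohort)
  idx <- which(upper.tri(cc), arr.ind = TRUE)
  data.frame(cohort1 = colnames(cc)[idx[, 1]], cohort2 = colnames(cc)[idx[, 2]],
             r = cc[idx])
}

#' Sample skewness (adjusted Fisher-Pearson)
#'
#' `g1 * sqrt(n (n - 1)) / (n - 2)` with `g1 = m3 / m2^(3/2)`. A positive
#' skew of the residual-correlation distribution is the qualitative
#' signature of fitness epistasis (an excess of large positive residuals).
#'
#' @param x numeric vector, length >= 3.
#' @return skewness.
#' @export
residual_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) stop_data("skewness needs >= 3 values")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop_data("skewness undefined for zero-variance input")
  g1 <- mean((x - m)^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Combine cohort scans by meta-analysis
#'
#' Aligns the cohorts' scan results on (chrom, bin_i, bin_j), requires an
#' identical pair grid, and returns the per-pair weighted-Z meta-analysis
#' with Cochran's Q plus global diagnostics (genomic-control lambda,
#' per-cohort residual skewness, pairwise cohort Z correlations).
#'
#' @param scans list of `scan_result` objects (>= 1), one per cohort.
#' @param n_by_cohort sample sizes, same length/order.
#' @param sigma_by_cohort per-cohort null scales (`sigma_hat`); required for
#'   Q when there are >= 2 cohorts.
#' @return list of class `meta_result`: `pairs` (meta table), `lambda_gc`,
#'   `skewness`, `z_correlations`.
#' @export
run_meta <- function(scans, n_by_cohort, sigma_by_cohort = NULL) {
  K <- length(scans)
  if (K < 1) stop_data("need >= 1 cohort scan")
  if (length(n_by_cohort) != K) stop_data("one sample size per cohort required")
  key <- function(s) paste(s$chrom, s$bin_i, s$bin_j)
  k0 <- key(scans[[1]])
  for (k in seq_len(K)) {
    kk <- key(scans[[k]])
    if (length(kk) != length(k0) || any(kk != k0)) {
      first <- if (length(kk) != length(k0)) "pair-count mismatch"
        else paste("first divergent pair:", k0[which(kk != k0)[1]])
      stop_data("cohort ", k, " is not on the shared bin grid (", first, ")")
    }
  }
  zmat <- do.call(cbind, lapply(scans, `[[`, "z"))
  colnames(zmat) <- names(scans) %||% paste0("cohort", seq_len(K))
  meta <- weighted_z_meta(zmat, n_by_cohort)
  base <- scans[[1]][, c("chrom", "bin_i", "bin_j", "mid_bp_i", "mid_bp_j", "d_cM")]
  pairs <- cbind(base, meta)
  if (K >= 2) {
    if (is.null(sigma_by_cohort)) stop_data("sigma_by_cohort required for Cochran's Q")
    bmat <- do.call(cbind, lapply(scans, `[[`, "beta_res"))
    pairs <- cbind(pairs, cochran_q(bmat, sigma_by_cohort^2))
  }
  pairs$passes_distance_filter <- scans[[1]]$passes_distance_filter
  structure(list(pairs = pairs,
                 lambda_gc = genomic_control_lambda(meta$z_meta),
                 skewness = vapply(scans, function(s) residual_skewness(s$beta_res), 0),
                 z_correlations = if (K >= 2) cohort_z_correlation(zmat) else NULL),
            class = "meta_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' QQ-plot coordinates for scan or meta p-values
#'
#' @param p p-values.
#' @return data.frame with `expected` and `observed` -log10(p), sorted.
#' @export
qq_data <- function(p) {
  p <- sort(p[is.finite(p)])
  n <- length(p)
  data.frame(expected = -log10((seq_len(n) - 0.5) / n), observed = -log10(p))
}
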