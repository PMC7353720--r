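#' Z-test of residual ancestry correlations
#'
#' Each pair's averaged residual correlation is divided by the null scale
#' (SD of cross-chromosome correlations) to give a Z-score, with a
#' two-sided normal p-value `P = 2 (1 - Phi(|Z|))`.
#'
#' @param rm a `residual_matrix` from [residual_correlations()].
#' @param scale a `null_scale` from [estimate_null_scale()].
#' @return `scan_result` data.frame, one row per unordered bin pair:
#'   `chrom`, `bin_i`, `bin_j`, `mid_bp_i`, `mid_bp_j`, `d_cM`, `beta`,
#'   `beta_res`, `z`, `p`, `passes_distance_filter`, `significant` (the last
#'   two initialised FALSE / NA until [distance_filter()] and a threshold
#'   are applied).
#' @export
z_test <- function(rm, scale) {
  stopifnot(inherits(rm, "residual_matrix"))
  if (!is.finite(scale$sigma_hat) || scale$sigma_hat <= 0)
    stop_data("null scale sigma_hat must be positive")
  M <- length(rm$bin_ids)
  ut <- which(upper.tri(rm$beta_res), arr.ind = TRUE)
  i <- ut[, 1]; j <- ut[, 2]
  beta_res <- rm$beta_res[ut]
  keep <- is.finite(beta_res)
  i <- i[keep]; j <- j[keep]; beta_res <- beta_res[keep]
  z <- beta_res / scale$sigma_hat
  out <- data.frame(chrom = rm$chrom, bin_i = rm$bin_ids[i], bin_j = rm$bin_ids[j],
                    mid_bp_i = rm$mid_bp[i], mid_bp_j = rm$mid_bp[j],
                    d_cM = rm$d_cM[cbind(i, j)], beta = rm$beta[cbind(i, j)],
                    beta_res = beta_res, z = z,
                    p = 2 * pnorm(-abs(z)),
                    passes_distance_filter = FALSE, significant = FALSE)
  attr(out, "sigma_hat") <- scale$sigma_hat
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Effective number of independent bins (eigenvalue method)
#'
#' Li & Ji-style effective number of independent variables among correlated
#' bins: with eigenvalues `lambda` of the bin correlation matrix,
#' `k = sum(I(lambda >= 1) + (lambda - floor(lambda)))`, floored to an
#' integer.
#'
#' @param beta symmetric bin correlation matrix (or a `correlation_matrix`).
#' @return integer `k`, `1 <= k <= nrow(beta)`.
#' @export
effective_bins <- function(beta) {
  if (inherits(beta, "correlation_matrix")) beta <- beta$beta
  if (!isSymmetric(unname(beta), tol = 1e-8)) stop_data("correlation matrix must be symmetric")
  lam <- eigen(beta, symmetric = TRUE, only.values = TRUE)$values
  lam <- round(pmax(lam, 0), 10)  # guard fp jitter around integers
  k <- floor(sum((lam >= 1) + (lam - floor(lam))) + 1e-9)
  max(1L, as.integer(k))
}

#' Total number of independent within-chromosome pair tests
#'
#' `sum_i k_i (k_i - 1) / 2` over chromosomes.
#'
#' @param k vector of per-chromosome effective bin counts (all >= 1).
#' @return integer count (>= 1 enforced by the Bonferroni step).
#' @export
total_independent_tests <- function(k) {
  if (any(k < 1)) stop_data("all k must be >= 1")
  sum(k * (k - 1) / 2)
}

#' Bonferroni-corrected significance level
#'
#' @param n_independent number of independent tests (>= 1).
#' @param alpha family-wise level.
#' @return `alpha / n_independent`.
#' @export
bonferroni_threshold <- function(n_independent, alpha = 0.05) {
  if (n_independent < 1) stop_data("n_independent must be >= 1")
  alpha / n_independent
}

#' Flag pairs beyond the minimum genetic distance
#'
#' Pairs closer than `min_cM` are retained for audit but flagged out: at
#' short range residual admixture LD may not be fully removed by the decay
#' fit. The bound is strict ("less than `min_cM`" is excluded), so
#' `d == min_cM` passes.
#'
#' @param scan a `scan_result`.
#' @param min_cM minimum genetic distance (default 50 cM).
#' @return the `scan_result` with `passes_distance_filter` set.
#' @export
distance_filter <- function(scan, min_cM = 50) {
  scan$passes_distance_filter <- scan$d_cM >= min_cM
  scan
}

#' Declare significant pairs
#'
#' @param scan a `scan_result` (after [distance_filter()]).
#' @param alpha_corrected per-test significance level.
#' @return the `scan_result` with `significant` set
#'   (`p < alpha_corrected` and distance flag).
#' @export
declare_significant <- function(scan, alpha_corrected) {
  scan$significant <- scan$passes_distance_filter & scan$p < alpha_corrected
  attr(scan, "alpha_corrected") <- alpha_corrected
  scan
}

#' Merge significant bin pairs into region pairs
#'
#' Builds connected components over the significant pairs of one
#' chromosome: two pairs are connected when both endpoints lie within
#' `gap_bins` bins of each other (in manifest order). Each component is
#' reported as a pair of bounding regions.
#'
#' @param scan a `scan_result` with `significant` set, single chromosome.
#' @param manifest a [bin_manifest()].
#' @param gap_bins endpoint adjacency tolerance in bins.
#' @param telomere_annot optional exclusion annotation
#'   (see [read_bed_exclusions()]) used only to flag components whose
#'   regions come within 2 Mb of an annotated interval.
#' @return data.frame of class `region_pair`: `chrom`, region bounds in bp
#'   and Mb, `n_pairs`, `min_p`, `telomere_flag`.
#' @export
merge_region_pairs <- function(scan, manifest, gap_bins = 1, telomere_annot = NULL) {
  sig <- scan[scan$significant, , drop = FALSE]
  empty <- data.frame(chrom = character(0), region1_start_bp = numeric(0),
                      region1_end_bp = numeric(0), region2_start_bp = numeric(0),
                      region2_end_bp = numeric(0), region1_mb = character(0),
                      region2_mb = character(0), n_pairs = integer(0),
                      min_p = numeric(0), telomere_flag = logical(0))
  if (nrow(sig) == 0) return(structure(empty, class = c("region_pair", "data.frame")))
  if (length(unique(sig$chrom)) > 1) stop_data("merge_region_pairs expects a single chromosome")
  man <- manifest[as.character(manifest$chrom) == as.character(sig$chrom[1]), ]
  pos <- setNames(seq_len(nrow(man)), man$bin_id)
  ii <- pos[sig$bin_i]; jj <- pos[sig$bin_j]
  # canonical orientation: region 1 holds the lower bin index
  lo <- pmin(ii, jj); hi <- pmax(ii, jj)
  np <- length(lo)
  adj <- which(outer(lo, lo, function(a, b) abs(a - b) <= gap_bins) &
               outer(hi, hi, function(a, b) abs(a - b) <= gap_bins), arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(data.frame(from = adj[, 1], to = adj[, 2]),
                                     directed = FALSE,
                                     vertices = data.frame(name = seq_len(np)))
  comp <- igraph::components(g)$membership
  rows <- lapply(split(seq_len(np), comp), function(members) {
    r1 <- range(c(man$start_bp[lo[members]], man$end_bp[lo[members]]))
    r2 <- range(c(man$start_bp[hi[members]], man$end_bp[hi[members]]))
    data.frame(chrom = sig$chrom[1],
               region1_start_bp = r1[1], region1_end_bp = r1[2],
               region2_start_bp = r2[1], region2_end_bp = r2[2],
               region1_mb = sprintf("%.2f-%.2f", r1[1] / 1e6, r1[2] / 1e6),
               region2_mb = sprintf("%.2f-%.2f", r2[1] / 1e6, r2[2] / 1e6),
               n_pairs = length(members), min_p = min(sig$p[members]),
               telomere_flag = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(telomere_annot) && nrow(telomere_annot) > 0) {
    near <- function(s, e) {
      any(telomere_annot$chrom == out$chrom[1] &
          s <= telomere_annot$end_bp + 2e6 & e >= telomere_annot$start_bp - 2e6)
    }
    out$telomere_flag <- vapply(seq_len(nrow(out)), function(r)
      near(out$region1_start_bp[r], out$region1_end_bp[r]) ||
      near(out$region2_start_bp[r], out$region2_end_bp[r]), TRUE)
  }
  structure(out, class = c("region_pair", "data.frame"))
}

#' Cap -log10(p) values for heatmap export
#'
#' Heatmap convention: -log10(p) above `cap` is set to `cap`.
#'
#' @param p p-values.
#' @param cap cap value (default 6).
#' @return capped -log10(p) vector.
#' @export
neglog10_capped <- function(p, cap = 6) pmin(-log10(p), cap)
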