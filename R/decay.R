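#' Fit the per-locus admixture-LD decay curve
#'
#' For one locus `i`, fits `f(d) = a0 + a1 * exp(-a2 * d)` by least squares
#' to the observed ancestry correlations `beta_ij` against the genetic
#' distances `d_ij` (cM) to every other locus on the chromosome. `a0`
#' represents background LD between effectively unlinked loci and is left
#' unconstrained (it can be slightly negative by sampling); `a1, a2 >= 0`
#' keep the curve a decaying exponential.
#'
#' The fit profiles out `(a0, a1)`: for fixed `a2` these solve a linear
#' least-squares problem in closed form (with `a1` clamped at 0 when the
#' unconstrained slope is negative), so the objective reduces to a
#' one-dimensional function of `a2`, minimised by a coarse log-spaced grid
#' followed by Brent refinement. This is deterministic and has no iterative
#' convergence failures; `converged` is FALSE only when the data are
#' insufficient.
#'
#' @param locus bin id (bookkeeping only).
#' @param betas correlations of this locus with the other loci.
#' @param distances genetic distances in cM, same length as `betas`.
#' @param a2_max upper bound of the `a2` search (per cM); 3/cM corresponds
#'   to decay over well under a centiMorgan, far steeper than any plausible
#'   admixture-LD curve.
#' @return one-row data.frame of class `decay_fit`: `locus`, `a0`, `a1`,
#'   `a2`, `sse`, `converged`, `n_points`.
#' @export
fit_locus_decay <- function(locus, betas, distances, a2_max = 3) {
  ok <- is.finite(betas) & is.finite(distances)
  betas <- betas[ok]; distances <- distances[ok]
  if (length(betas) < 10 || length(unique(distances)) < 3)
    stop_data("locus ", locus, ": need >= 10 points with >= 3 distinct distances")
  grid <- decay_a2_grid(a2_max)
  sse_grid <- vapply(grid, function(a) decay_profile(a, betas, distances)[3], 0)
  k <- which.min(sse_grid)
  decay_refine(locus, betas, distances, grid, k, sse_grid[k])
}

#' Fit the decay curve at every locus of a chromosome
#'
#' Runs [fit_locus_decay()] for each retained bin against all other bins on
#' the same chromosome (all pairs enter the fit, including those a later
#' distance filter removes from testing).
#'
#' @param cm a `correlation_matrix` from [within_chromosome_correlations()].
#' @return data.frame of class `decay_fit`, one row per locus.
#' @export
fit_chromosome_decay <- function(cm, a2_max = 3) {
  stopifnot(inherits(cm, "correlation_matrix"))
  M <- length(cm$bin_ids)
  if (M - 1 < 10) {  # small chromosome: plain per-locus path
    rows <- lapply(seq_len(M), function(i)
      fit_locus_decay(cm$bin_ids[i], cm$beta[i, -i], cm$d_cM[i, -i]))
    out <- do.call(rbind, rows)
    class(out) <- c("decay_fit", "data.frame")
    return(out)
  }
  # vectorised coarse grid: profiled SSE for all loci at once per a2 value,
  # using row-sum sufficient statistics with the diagonal removed
  beta <- cm$beta; D <- cm$d_cM
  n <- M - 1
  Sy <- rowSums(beta) - 1
  Syy <- rowSums(beta^2) - 1
  grid <- decay_a2_grid(a2_max)
  sse <- matrix(NA_real_, M, length(grid))
  for (g in seq_along(grid)) {
    E <- exp(-grid[g] * D)
    Sx <- rowSums(E) - 1
    Sxx <- rowSums(E^2) - 1
    Sxy <- rowSums(beta * E) - 1
    vx <- Sxx - Sx^2 / n
    a1 <- ifelse(vx < 1e-14, 0, pmax(0, (Sxy - Sx * Sy / n) / vx))
    a0 <- (Sy - a1 * Sx) / n
    sse[, g] <- Syy + n * a0^2 + a1^2 * Sxx + 2 * a0 * a1 * Sx -
      2 * a0 * Sy - 2 * a1 * Sxy
  }
  k <- max.col(-sse, ties.method = "first")
  rows <- lapply(seq_len(M), function(i)
    decay_refine(cm$bin_ids[i], beta[i, -i], D[i, -i], grid, k[i], sse[i, k[i]]))
  out <- do.call(rbind, rows)
  class(out) <- c("decay_fit", "data.frame")
  out
}

decay_a2_grid <- function(a2_max) c(0, exp(seq(log(1e-4), log(a2_max), length.out = 60)))

# profiled objective at one a2: returns c(a0, a1, sse)
decay_profile <- function(a2, betas, distances) {
  e <- exp(-a2 * distances)
  ve <- var(e)
  if (ve < 1e-14) {
    a1 <- 0; a0 <- mean(betas)
  } else {
    a1 <- cov(betas, e) / ve
    if (a1 < 0) a1 <- 0
    a0 <- mean(betas) - a1 * mean(e)
  }
  c(a0, a1, sum((betas - a0 - a1 * e)^2))
}

# Brent refinement around grid point k, falling back to the grid optimum
decay_refine <- function(locus, betas, distances, grid, k, sse_k) {
  lo <- grid[max(1, k - 1)]; hi <- grid[min(length(grid), k + 1)]
  a2 <- if (lo == hi) lo else
    optimize(function(a) decay_profile(a, betas, distances)[3], c(lo, hi), tol = 1e-10)$minimum
  if (decay_profile(a2, betas, distances)[3] > sse_k) a2 <- grid[k]
  p <- decay_profile(a2, betas, distances)
  structure(data.frame(locus = locus, a0 = p[1], a1 = p[2], a2 = a2,
                       sse = p[3], converged = TRUE, n_points = length(betas)),
            class = c("decay_fit", "data.frame"))
}

#' Predict admixture LD under the null decay model
#'
#' @param fit a one-row `decay_fit` (or anything with `a0`, `a1`, `a2`).
#' @param d_cM genetic distance(s) in cM.
#' @return `a0 + a1 * exp(-a2 * d)`.
#' @export
predict_null_ld <- function(fit, d_cM) {
  fit$a0 + fit$a1 * exp(-fit$a2 * d_cM)
}

#' Residual (excess) ancestry correlations after removing admixture LD
#'
#' For each ordered pair `(i, j)` the directional residual is
#' `beta_ij - f_i(d_ij)` using locus `i`'s own fitted curve; the final
#' departure is the average of the two directions, which symmetrises the
#' matrix exactly. Pairs with a non-converged endpoint fit are masked (NA)
#' and counted.
#'
#' @param cm a `correlation_matrix`.
#' @param fits `decay_fit` rows for every locus of `cm` (from
#'   [fit_chromosome_decay()]).
#' @return object of class `residual_matrix`: `chrom`, `bin_ids`, `beta`,
#'   `beta_res` (symmetric average), `res_dir` (directional residuals,
#'   row = predicting locus), `d_cM`, `mid_bp`, `n_masked`.
#' @export
residual_correlations <- function(cm, fits) {
  idx <- match(cm$bin_ids, fits$locus)
  if (anyNA(idx)) stop_data("missing decay fit for some loci")
  fits <- fits[idx, ]
  pred <- fits$a0 + fits$a1 * exp(-fits$a2 * cm$d_cM)  # row i: locus i's curve
  res_dir <- cm$beta - pred
  bad <- !fits$converged
  res_dir[bad, ] <- NA_real_
  res_dir[, bad] <- NA_real_
  beta_res <- (res_dir + t(res_dir)) / 2
  diag(beta_res) <- NA_real_
  structure(list(chrom = cm$chrom, bin_ids = cm$bin_ids, beta = cm$beta,
                 beta_res = beta_res, res_dir = res_dir, d_cM = cm$d_cM,
                 mid_bp = cm$mid_bp, n_samples = cm$n_samples,
                 n_masked = sum(bad)),
            class = "residual_matrix")
}
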