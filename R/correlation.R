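#' Within-chromosome local-ancestry correlations
#'
#' Pearson correlation of diploid ancestry dosages over samples for every
#' pair of bins on the same chromosome. Zero-variance bins (e.g. fixed
#' ancestry) cannot enter a correlation and are excluded and reported via
#' the `excluded_bins` field rather than propagating NaN.
#'
#' @param la a [local_ancestry()].
#' @param manifest a [bin_manifest()] matching `la$bin_ids`.
#' @return named list (one element per chromosome) of `correlation_matrix`
#'   objects with fields `chrom`, `bin_ids`, `beta` (symmetric, unit
#'   diagonal), `d_cM` (pairwise genetic distances), `n_samples`,
#'   `excluded_bins`.
#' @export
within_chromosome_correlations <- function(la, manifest) {
  if (!setequal(la$bin_ids, manifest$bin_id))
    stop_data("ancestry matrix bin ids do not match the manifest")
  if (la$n_samples < 3) stop_data("need >= 3 samples to estimate correlations")
  lapply(setNames(nm = as.character(unique(manifest$chrom))), function(ch) {
    man <- manifest[manifest$chrom == ch, ]
    if (nrow(man) < 2) stop_data("need >= 2 bins on chromosome ", ch)
    x <- la$dosage[, man$bin_id, drop = FALSE]
    v <- apply(x, 2, var)
    excluded <- man$bin_id[v == 0]
    keep <- v > 0
    x <- x[, keep, drop = FALSE]
    man <- man[keep, ]
    beta <- cor(x)
    structure(list(chrom = ch, bin_ids = man$bin_id, beta = beta,
                   d_cM = abs(outer(man$mid_cM, man$mid_cM, "-")),
                   mid_bp = man$mid_bp, mid_cM = man$mid_cM,
                   n_samples = la$n_samples, excluded_bins = excluded),
              class = "correlation_matrix")
  })
}

#' Null scale: SD of cross-chromosome ancestry correlations
#'
#' Loci on different chromosomes are effectively at infinite genetic
#' distance, so their ancestry correlations sample the null distribution of
#' the correlation estimate. Their standard deviation serves as the
#' denominator of the epistasis Z-test. When the number of cross-chromosome
#' bin pairs exceeds `max_pairs`, a seeded uniform subsample is used and
#' recorded.
#'
#' @param la a [local_ancestry()].
#' @param manifest a [bin_manifest()] with >= 2 chromosomes.
#' @param max_pairs cap on the number of pairs (default 2e6).
#' @param seed seed for the subsample, recorded in the result.
#' @return object of class `null_scale`: `sigma_hat`, `n_pairs_used`,
#'   `subsample_seed` (NULL when no subsampling happened).
#' @export
estimate_null_scale <- function(la, manifest, max_pairs = 2e6, seed = 1L) {
  chrom <- manifest$chrom[match(la$bin_ids, manifest$bin_id)]
  if (anyNA(chrom)) stop_data("ancestry matrix bin ids do not match the manifest")
  if (length(unique(chrom)) < 2)
    stop_data("null scale needs >= 2 chromosomes")
  x <- la$dosage
  v <- apply(x, 2, var)
  x <- x[, v > 0, drop = FALSE]
  chrom <- chrom[v > 0]
  n <- nrow(x)
  z <- scale(x)  # unit-variance columns; corr = crossprod / (n - 1)
  counts <- table(chrom)
  total <- (ncol(x)^2 - sum(counts^2)) / 2
  if (total < 1) stop_data("no cross-chromosome bin pairs available")
  subsampled <- total > max_pairs
  if (!subsampled) {
    chs <- unique(chrom)
    vals <- list()
    for (a in seq_along(chs)) for (b in seq_along(chs)) if (a < b) {
      cc <- crossprod(z[, chrom == chs[a], drop = FALSE],
                      z[, chrom == chs[b], drop = FALSE]) / (n - 1)
      vals[[length(vals) + 1]] <- as.vector(cc)
    }
    vals <- unlist(vals)
  } else {
    vals <- with_seed(seed, {
      got <- numeric(0)
      chunk <- 4000L  # bounds the n x chunk working matrix
      while (length(got) < max_pairs) {
        i <- sample.int(ncol(x), chunk, replace = TRUE)
        j <- sample.int(ncol(x), chunk, replace = TRUE)
        ok <- chrom[i] != chrom[j]
        i <- i[ok]; j <- j[ok]
        if (length(i))
          got <- c(got, colSums(z[, i, drop = FALSE] * z[, j, drop = FALSE]) / (n - 1))
      }
      got[seq_len(max_pairs)]
    })
  }
  sigma <- sd(vals)
  if (!is.finite(sigma) || sigma == 0)
    stop_data("degenerate null scale: cross-chromosome correlations have zero spread")
  structure(list(sigma_hat = sigma, n_pairs_used = length(vals),
                 subsample_seed = if (subsampled) seed else NULL),
            class = "null_scale")
}
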