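#' Positional enrichment of hits in a target region
#'
#' Tests whether a target region carries more positional hits (e.g.
#' GWAS-catalog associations) than expected. The chromosome minus the
#' target is tiled into non-overlapping windows of the target's bp length
#' (partial leftover windows dropped); the Z-score is the observed target
#' count minus the mean window count, divided by the standard deviation of
#' the window counts, with a one-sided upper p-value.
#'
#' @param hits data.frame with columns `chrom` and `bp` (and optionally a
#'   label).
#' @param target `list(chrom =, start_bp =, end_bp =)`.
#' @param chrom_length chromosome length in bp.
#' @return list of class `enrichment_result`: `z`, `p`, `observed`,
#'   `expected`, `sd`, `n_windows`.
#' @export
region_enrichment <- function(hits, target, chrom_length) {
  if (target$start_bp < 1 || target$end_bp > chrom_length || target$start_bp >= target$end_bp)
    stop_config("target must lie within the chromosome")
  h <- hits[as.character(hits$chrom) == as.character(target$chrom), , drop = FALSE]
  if (any(h$bp < 1 | h$bp > chrom_length)) stop_data("hit positions outside chromosome bounds")
  L <- target$end_bp - target$start_bp + 1
  windows <- list()
  for (seg in list(c(1, target$start_bp - 1), c(target$end_bp + 1, chrom_length))) {
    if (seg[2] <= seg[1]) next
    k <- floor((seg[2] - seg[1] + 1) / L)
    if (k >= 1) {
      s <- seg[1] + (seq_len(k) - 1) * L
      windows[[length(windows) + 1]] <- cbind(s, s + L - 1)
    }
  }
  w <- do.call(rbind, windows)
  if (is.null(w) || nrow(w) < 5)
    stop_data("fewer than 5 reference windows; target too large for the chromosome")
  counts <- vapply(seq_len(nrow(w)),
                   function(r) sum(h$bp >= w[r, 1] & h$bp <= w[r, 2]), 0L)
  observed <- sum(h$bp >= target$start_bp & h$bp <= target$end_bp)
  sdv <- sd(counts)
  if (sdv == 0) stop_data("window hit counts have zero spread; enrichment Z undefined")
  z <- (observed - mean(counts)) / sdv
  structure(list(z = z, p = pnorm(z, lower.tail = FALSE), observed = observed,
                 expected = mean(counts), sd = sdv, n_windows = nrow(w)),
            class = "enrichment_result")
}
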