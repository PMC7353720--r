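#' Ancestry-switch rate in a genomic interval (ANCAEC)
#'
#' Average number of crossovers between African and European chromosomes
#' per centiMorgan in an interval. Per individual, events are summed over
#' adjacent bin pairs as `|dosage[b+1] - dosage[b]|` (a 0 -> 2 change counts
#' as two events: diploid dosage conflates the two haplotypes and the
#' absolute difference is the minimal event count consistent with the
#' data); the rate is the mean over individuals divided by the interval's
#' cM length.
#'
#' @param la a [local_ancestry()].
#' @param manifest a [bin_manifest()].
#' @param interval `list(chrom =, start_bp =, end_bp =)`; bins whose
#'   `mid_bp` falls inside are used (>= 2 required).
#' @return object of class `crossover_stats`: `interval`, `cM_length`,
#'   `ancaec_per_cM`, `events` (per-individual counts), `n_bins`.
#' @export
count_ancestry_switches <- function(la, manifest, interval) {
  man <- manifest[as.character(manifest$chrom) == as.character(interval$chrom) &
                  manifest$mid_bp >= interval$start_bp &
                  manifest$mid_bp <= interval$end_bp, ]
  if (nrow(man) < 2) stop_data("interval contains fewer than 2 bins")
  x <- la$dosage[, man$bin_id, drop = FALSE]
  events <- rowSums(abs(x[, -1, drop = FALSE] - x[, -ncol(x), drop = FALSE]))
  cm <- man$mid_cM[nrow(man)] - man$mid_cM[1]
  if (cm <= 0) stop_data("interval has zero genetic length")
  structure(list(interval = interval, cM_length = cm,
                 ancaec_per_cM = mean(events) / cm, events = events,
                 n_bins = nrow(man)),
            class = "crossover_stats")
}

#' Deficit test for ancestry crossovers between two regions
#'
#' Compares the target interval's ancestry-switch rate (ANCAEC per cM)
#' against the genome-wide distribution of the same rate in non-overlapping
#' reference windows of matched genetic length, tiled over the genome after
#' removing the excluded intervals (normally the two candidate regions
#' themselves). Under no epistasis the target rate is an ordinary draw from
#' that distribution, taken as approximately normal; the test is one-sided
#' for a deficit.
#'
#' @param target `crossover_stats` of the inter-region interval.
#' @param la a [local_ancestry()].
#' @param manifest a [bin_manifest()].
#' @param excluded list of intervals (`chrom`, `start_bp`, `end_bp`) whose
#'   bins are removed before tiling; the target interval should be among
#'   them.
#' @param min_windows minimum number of reference windows (default 10).
#' @return list of class `deficit_test`: `z`, `p` (one-sided, deficit),
#'   `target_rate`, `ref_mean`, `ref_sd`, `n_windows`, `window_rates`.
#' @export
deficit_test <- function(target, la, manifest, excluded = list(), min_windows = 10) {
  drop <- rep(FALSE, nrow(manifest))
  for (iv in excluded)
    drop <- drop | (as.character(manifest$chrom) == as.character(iv$chrom) &
                    manifest$mid_bp >= iv$start_bp & manifest$mid_bp <= iv$end_bp)
  man <- manifest[!drop, ]
  len <- target$cM_length
  rates <- numeric(0)
  for (ch in unique(man$chrom)) {
    dch <- man[man$chrom == ch, ]
    # windows must not span an excluded interval: the hole would contribute
    # genetic length but no observable switches, deflating the window's rate
    cut_after <- rep(FALSE, nrow(dch))
    if (nrow(dch) > 1) for (iv in excluded) {
      if (as.character(iv$chrom) != as.character(ch)) next
      cut_after <- cut_after | c(iv$end_bp > dch$mid_bp[-nrow(dch)] &
                                   iv$start_bp < dch$mid_bp[-1], FALSE)
    }
    seg <- cumsum(c(0, utils::head(cut_after, -1)))
    for (d in split(dch, seg)) {
      i <- 1
      while (i < nrow(d)) {
        # grow a run of consecutive retained bins until it spans >= len cM
        j <- i
        while (j < nrow(d) && d$mid_cM[j] - d$mid_cM[i] < len) j <- j + 1
        if (d$mid_cM[j] - d$mid_cM[i] >= len && j > i) {
          x <- la$dosage[, d$bin_id[i:j], drop = FALSE]
          ev <- rowSums(abs(x[, -1, drop = FALSE] - x[, -ncol(x), drop = FALSE]))
          rates <- c(rates, mean(ev) / (d$mid_cM[j] - d$mid_cM[i]))
          i <- j + 1
        } else break
      }
    }
  }
  if (length(rates) < min_windows)
    stop_data("only ", length(rates), " reference windows available (need ", min_windows, ")")
  mu <- mean(rates); sdv <- sd(rates)
  if (sdv == 0) stop_data("reference window rates are constant")
  z <- (target$ancaec_per_cM - mu) / sdv
  structure(list(z = z, p = pnorm(z), target_rate = target$ancaec_per_cM,
                 ref_mean = mu, ref_sd = sdv, n_windows = length(rates),
                 window_rates = rates),
            class = "deficit_test")
}
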