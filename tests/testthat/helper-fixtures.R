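# shared fixtures and a cross-test cache for the heavier simulation studies

one_chrom <- function(morgans = 2, bp = 2e8) {
  data.frame(length_morgans = morgans, length_bp = bp)
}

two_chrom <- function(morgans = 2, bp = 2e8) {
  data.frame(length_morgans = c(morgans, morgans), length_bp = c(bp, bp))
}

# small deterministic dosage matrix with plausible ancestry structure
toy_ancestry <- function(n = 40, bins = 12, chroms = 2, seed = 7) {
  set.seed(seed)
  x <- matrix(rbinom(n * bins * chroms, 2, 0.7), n)
  colnames(x) <- sprintf("chr%d_bin%05d", rep(seq_len(chroms), each = bins),
                         rep(seq_len(bins), chroms))
  la <- local_ancestry(x, cohort = "toy")
  man <- bin_manifest(data.frame(
    bin_id = colnames(x), chrom = rep(seq_len(chroms), each = bins),
    start_bp = rep((seq_len(bins) - 1) * 4e5 + 1, chroms),
    end_bp = rep(seq_len(bins) * 4e5, chroms),
    mid_bp = rep((seq_len(bins) - 1) * 4e5 + 2e5, chroms),
    mid_cM = rep((seq_len(bins) - 1) * 4e5 + 2e5, chroms) / 1e6))
  list(la = la, manifest = man)
}

# null scale from two independent replicates of the same scenario: their bin
# columns are independent over the shared sample index, i.e. cross-chromosome
# pairs in all but name; estimated through the package's own machinery by
# relabelling one replicate's bins as a second chromosome.
cross_replicate_scale <- function(dosage_a, dosage_b, manifest) {
  man2 <- as.data.frame(manifest)
  man2$chrom <- man2$chrom + max(manifest$chrom)
  man2$bin_id <- paste0("x_", man2$bin_id)
  db <- dosage_b
  colnames(db) <- man2$bin_id
  comb <- local_ancestry(cbind(dosage_a, db))
  estimate_null_scale(comb, bin_manifest(rbind(as.data.frame(manifest), man2)),
                      max_pairs = 3e5, seed = 1L)
}

# memoised store for simulation studies shared between test blocks
.study_cache <- new.env(parent = emptyenv())

# Calibration study: null replicates at n = 2000, t = 8, m = 0.8, one
# 2-Morgan chromosome, 400-kb bins. Replicate r's Z-test uses a null scale
# estimated from cross-replicate pairs (r vs r - 1; replicate 1 pairs with
# the last replicate). Streams replicates to bound memory; returns pooled
# summaries.
null_study <- function(n_rep = 200, n = 2000) {
  key <- paste0("null_", n_rep, "_", n)
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  chr <- one_chrom()
  rej <- 0; tot <- 0
  z_sub <- list(); a2_pool <- list(); sigmas <- numeric(n_rep)
  first_dosage <- NULL; prev_dosage <- NULL; pending <- NULL
  manifest <- NULL
  ztest_rep <- function(rmx, sigma_obj, r) {
    sc <- distance_filter(z_test(rmx, sigma_obj))
    far <- sc[sc$passes_distance_filter, ]
    rej <<- rej + sum(far$p < 0.05)
    tot <<- tot + nrow(far)
    z_sub[[length(z_sub) + 1]] <<- far$z[seq(1, nrow(far), by = 5)]
    sigmas[r] <<- sigma_obj$sigma_hat
  }
  for (r in seq_len(n_rep)) {
    sim <- simulate_population(sim_config(n, 8, 0.8, chr, seed = 9000 + r))
    if (is.null(manifest)) manifest <- sim$manifest
    cm <- within_chromosome_correlations(sim$ancestry, sim$manifest)[[1]]
    fits <- fit_chromosome_decay(cm)
    a2_pool[[r]] <- fits$a2
    rmx <- residual_correlations(cm, fits)
    if (r == 1) {
      first_dosage <- sim$ancestry$dosage
      pending <- rmx  # tested once the last replicate provides its pair
    } else {
      ztest_rep(rmx, cross_replicate_scale(sim$ancestry$dosage, prev_dosage,
                                           sim$manifest), r)
    }
    prev_dosage <- sim$ancestry$dosage
  }
  ztest_rep(pending, cross_replicate_scale(first_dosage, prev_dosage, manifest), 1L)
  out <- list(rejection_rate = rej / tot, n_pairs = tot,
              z = unlist(z_sub), a2 = unlist(a2_pool), sigmas = sigmas,
              lambda = genomic_control_lambda(unlist(z_sub)))
  .study_cache[[key]] <- out
  out
}
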