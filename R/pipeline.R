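#' Configuration for an end-to-end scan
#'
#' @param ancestry_path path to a local-ancestry TSV ([read_ancestry()]).
#' @param manifest_path path to a bin-manifest TSV ([read_manifest()]).
#' @param out_dir output directory (created if needed).
#' @param cohort cohort label.
#' @param exclusions_path optional telomere/centromere BED.
#' @param exclusion_radius_bp exclusion dilation radius.
#' @param sample_low,sample_high ancestry-proportion sample filter bounds.
#' @param min_cM minimum pair distance for declarations.
#' @param alpha family-wise significance level.
#' @param max_null_pairs cap on cross-chromosome pairs for the null scale.
#' @param gap_bins region-merge adjacency tolerance.
#' @param seed top-level seed (drives the null-scale subsample).
#' @return object of class `scan_config`.
#' @export
scan_config <- function(ancestry_path, manifest_path, out_dir, cohort = "cohort",
                        exclusions_path = NULL, exclusion_radius_bp = 2e6,
                        sample_low = 0.05, sample_high = 0.98, min_cM = 50,
                        alpha = 0.05, max_null_pairs = 2e6, gap_bins = 1,
                        seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must be in (0, 1)")
  for (p in c(ancestry_path, manifest_path, exclusions_path))
    if (!file.exists(p)) stop_config("input file not found: ", p)
  structure(as.list(environment()), class = "scan_config")
}

#' Run a full single-cohort epistasis scan
#'
#' Pipeline: sample filtering, within-chromosome correlations, per-locus
#' decay fits, residual correlations, cross-chromosome null scale, Z-test,
#' effective-test counting with Bonferroni correction, distance filtering,
#' significance declaration and region-pair merging. Every stage's output
#' is written under `out_dir` together with a run manifest (parameters,
#' seed, package version, per-stage counts); outputs carry no timestamps so
#' a rerun with the same config and seed is byte-identical.
#'
#' @param config a [scan_config()].
#' @return (invisibly) a list with the in-memory results: `scan`,
#'   `region_pairs`, `fits`, `null_scale`, `k`, `alpha_corrected`, `counts`.
#' @export
run_scan <- function(config) {
  stopifnot(inherits(config, "scan_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, paste0(...))

  la <- read_ancestry(config$ancestry_path, cohort = config$cohort)
  manifest <- read_manifest(config$manifest_path)
  say("stage=load samples=", la$n_samples, " bins=", nrow(manifest))

  if (!is.null(config$exclusions_path)) {
    annot <- read_bed_exclusions(config$exclusions_path)
    manifest <- apply_exclusions(manifest, annot, config$exclusion_radius_bp)
    say("stage=exclusions bins_dropped=", attr(manifest, "n_excluded") %||% 0,
        " bins_kept=", nrow(manifest))
    la <- local_ancestry(la$dosage[, manifest$bin_id, drop = FALSE], cohort = la$cohort)
  }

  la <- filter_samples(la, config$sample_low, config$sample_high)
  say("stage=sample_filter removed=", attr(la, "n_removed") %||% 0,
      " kept=", la$n_samples)

  cms <- within_chromosome_correlations(la, manifest)
  say("stage=correlations chromosomes=", length(cms), " zero_variance_bins=",
      sum(vapply(cms, function(cm) length(cm$excluded_bins), 0L)))

  scale <- estimate_null_scale(la, manifest, config$max_null_pairs, config$seed)
  say("stage=null_scale sigma_hat=", signif(scale$sigma_hat, 6),
      " pairs=", scale$n_pairs_used)

  scans <- list(); fits_all <- list(); k <- integer(0)
  for (ch in names(cms)) {
    fits <- fit_chromosome_decay(cms[[ch]])
    say("stage=decay_fit chrom=", ch, " loci=", nrow(fits),
        " non_converged=", sum(!fits$converged))
    rm_ <- residual_correlations(cms[[ch]], fits)
    scans[[ch]] <- z_test(rm_, scale)
    fits_all[[ch]] <- fits
    k[ch] <- effective_bins(cms[[ch]])
  }
  n_tests <- total_independent_tests(k)
  alpha_c <- bonferroni_threshold(max(n_tests, 1), config$alpha)
  say("stage=multiplicity k=", paste(k, collapse = ","),
      " independent_tests=", n_tests, " alpha_corrected=", signif(alpha_c, 6))

  scan <- do.call(rbind, scans)
  rownames(scan) <- NULL
  class(scan) <- c("scan_result", "data.frame")
  scan <- declare_significant(distance_filter(scan, config$min_cM), alpha_c)
  say("stage=test pairs=", nrow(scan),
      " pass_distance=", sum(scan$passes_distance_filter),
      " significant=", sum(scan$significant))

  regions <- do.call(rbind, lapply(split(scan, scan$chrom), function(s)
    merge_region_pairs(s, manifest, config$gap_bins)))
  rownames(regions) <- NULL
  say("stage=regions region_pairs=", nrow(regions))

  fits_df <- do.call(rbind, fits_all); rownames(fits_df) <- NULL
  data.table::fwrite(as.data.frame(fits_df), file.path(config$out_dir, "decay_fits.tsv"), sep = "\t")
  data.table::fwrite(as.data.frame(scan), file.path(config$out_dir, "scan.tsv"), sep = "\t")
  data.table::fwrite(as.data.frame(regions), file.path(config$out_dir, "region_pairs.tsv"), sep = "\t")
  jsonlite::write_json(list(sigma_hat = scale$sigma_hat,
                            n_pairs_used = scale$n_pairs_used),
                       file.path(config$out_dir, "null_scale.json"), auto_unbox = TRUE, digits = NA)
  run_manifest <- list(package = "admixepi",
                       version = as.character(utils::packageVersion("admixepi")),
                       cohort = config$cohort, seed = config$seed,
                       n_samples = la$n_samples, n_bins = nrow(manifest),
                       k = as.list(k), independent_tests = n_tests,
                       alpha = config$alpha, alpha_corrected = alpha_c,
                       min_cM = config$min_cM,
                       sample_filter = c(config$sample_low, config$sample_high))
  jsonlite::write_json(run_manifest, file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, file.path(config$out_dir, "scan.log"))

  invisible(list(scan = scan, region_pairs = regions, fits = fits_df,
                 null_scale = scale, k = k, alpha_corrected = alpha_c,
                 n_samples = la$n_samples, counts = log_lines))
}

#' Run a meta-analysis over completed cohort scans
#'
#' @param scan_dirs output directories of >= 2 [run_scan()] runs on the
#'   same bin grid.
#' @param out_dir output directory for the meta results.
#' @param min_cM distance filter for declaring meta-significant pairs.
#' @param alpha family-wise level; the corrected threshold reuses the
#'   maximum per-cohort independent-test count (the grids are identical).
#' @return (invisibly) list: `meta` (a `meta_result`), `significant`,
#'   `alpha_corrected`.
#' @export
run_meta_dirs <- function(scan_dirs, out_dir, min_cM = 50, alpha = 0.05) {
  if (length(scan_dirs) < 1) stop_config("need >= 1 scan directory")
  scans <- list(); ns <- numeric(0); sigmas <- numeric(0); ntests <- numeric(0)
  for (d in scan_dirs) {
    man <- jsonlite::read_json(file.path(d, "run_manifest.json"), simplifyVector = TRUE)
    s <- data.table::fread(file.path(d, "scan.tsv"), data.table = FALSE)
    class(s) <- c("scan_result", "data.frame")
    scans[[man$cohort]] <- s
    ns <- c(ns, man$n_samples)
    ntests <- c(ntests, man$independent_tests)
    sigmas <- c(sigmas, jsonlite::read_json(file.path(d, "null_scale.json"))$sigma_hat)
  }
  meta <- run_meta(scans, ns, sigmas)
  alpha_c <- bonferroni_threshold(max(ntests), alpha)
  pairs <- meta$pairs
  pairs$significant <- pairs$d_cM >= min_cM & pairs$p_meta < alpha_c
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(pairs, file.path(out_dir, "meta.tsv"), sep = "\t")
  diagnostics <- list(lambda_gc = meta$lambda_gc,
                      skewness = as.list(setNames(meta$skewness, names(scans))),
                      z_correlations = meta$z_correlations,
                      alpha_corrected = alpha_c)
  jsonlite::write_json(diagnostics, file.path(out_dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA)
  data.table::fwrite(qq_data(pairs$p_meta), file.path(out_dir, "qq.tsv"), sep = "\t")
  invisible(list(meta = meta, significant = pairs[pairs$significant, ],
                 alpha_corrected = alpha_c))
}
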