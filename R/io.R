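#' Local-ancestry dosage matrix
#'
#' Container for diploid local-ancestry dosages: per individual and genomic
#' bin, the number of African-derived alleles (0, 1 or 2; fractional values
#' from probabilistic ancestry calls are accepted as long as they stay in
#' `[0, 2]`).
#'
#' @param dosage numeric matrix, individuals x bins, with row names (sample
#'   ids) and column names (bin ids).
#' @param cohort cohort label.
#' @return object of class `local_ancestry` with fields `dosage`,
#'   `sample_ids`, `bin_ids`, `cohort`, `n_samples`.
#' @export
local_ancestry <- function(dosage, cohort = "cohort") {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage))) rownames(dosage) <- sprintf("ind%05d", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage))) stop_data("dosage matrix needs bin ids as column names")
  if (anyNA(dosage)) stop_data("missing dosage entries are not allowed")
  if (any(dosage < 0 | dosage > 2)) stop_data("dosages must lie in [0, 2]")
  structure(list(dosage = dosage, sample_ids = rownames(dosage),
                 bin_ids = colnames(dosage), cohort = cohort,
                 n_samples = nrow(dosage)),
            class = "local_ancestry")
}

#' @export
print.local_ancestry <- function(x, ...) {
  cat("<local_ancestry> cohort", x$cohort, ":", x$n_samples, "samples x",
      length(x$bin_ids), "bins\n")
  invisible(x)
}

#' Bin manifest
#'
#' Coordinates of the genomic bins a scan runs on: per bin its chromosome,
#' 1-based inclusive bp span, representative ("middle marker") bp position
#' and genetic-map position in cM.
#'
#' @param df data.frame with columns `bin_id`, `chrom`, `start_bp`, `end_bp`,
#'   `mid_bp`, `mid_cM`.
#' @return the validated data.frame with class `bin_manifest`.
#' @export
bin_manifest <- function(df) {
  need <- c("bin_id", "chrom", "start_bp", "end_bp", "mid_bp", "mid_cM")
  if (!all(need %in% names(df))) stop_data("manifest needs columns ", paste(need, collapse = ", "))
  df <- as.data.frame(df)[, need]
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, ]
    if (is.unsorted(d$start_bp) || is.unsorted(d$mid_cM))
      stop_data("bins on chromosome ", ch, " must be sorted with non-decreasing mid_cM")
    if (nrow(d) > 1 && any(d$start_bp[-1] <= d$end_bp[-nrow(d)]))
      stop_data("bins on chromosome ", ch, " overlap")
  }
  if (anyDuplicated(df$bin_id)) stop_data("duplicate bin ids")
  class(df) <- c("bin_manifest", "data.frame")
  df
}

#' Read / write a local-ancestry matrix as TSV
#'
#' Layout: first column `sample_id`, remaining columns one per bin id,
#' values in `[0, 2]`.
#'
#' @param path file path.
#' @param cohort cohort label attached on read.
#' @return [local_ancestry()] for the reader; invisible path for the writer.
#' @export
read_ancestry <- function(path, cohort = basename(path)) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- as.character(dt[[1]])
  if (any(colSums(!is.na(m)) == 0)) stop_data("all-missing bin column in ", path)
  local_ancestry(m, cohort = cohort)
}

#' @rdname read_ancestry
#' @param la a [local_ancestry()].
#' @export
write_ancestry <- function(la, path) {
  df <- data.frame(sample_id = la$sample_ids, la$dosage, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname bin_manifest
#' @param path file path.
#' @export
read_manifest <- function(path) {
  bin_manifest(data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE))
}

#' @rdname bin_manifest
#' @param manifest a `bin_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  data.table::fwrite(as.data.frame(manifest), path, sep = "\t")
  invisible(path)
}

#' Read a PLINK-style genetic map
#'
#' Whitespace-separated columns: chromosome, marker id, position in cM,
#' position in bp.
#'
#' @param path file path.
#' @return data.frame with columns `chrom`, `id`, `cM`, `bp`.
#' @export
read_genetic_map <- function(path) {
  dt <- data.table::fread(path, header = FALSE, data.table = FALSE)
  if (ncol(dt) < 4) stop_data("genetic map needs 4 columns (chrom, id, cM, bp)")
  setNames(dt[, 1:4], c("chrom", "id", "cM", "bp"))
}

#' Read telomere/centromere annotation from BED
#'
#' BED intervals (0-based, half-open) are converted to 1-based inclusive.
#'
#' @param path file path.
#' @return data.frame with columns `chrom`, `start_bp`, `end_bp`.
#' @export
read_bed_exclusions <- function(path) {
  dt <- data.table::fread(path, header = FALSE, data.table = FALSE)
  if (ncol(dt) < 3) stop_data("BED needs >= 3 columns")
  out <- data.frame(chrom = dt[[1]], start_bp = dt[[2]] + 1, end_bp = dt[[3]])
  if (any(out$start_bp > out$end_bp)) stop_data("invalid BED interval (start >= end)")
  out
}

#' Build fixed-width bins from a genetic map
#'
#' Tiles each chromosome with consecutive `bin_size_bp`-wide windows starting
#' at bp 1. Each bin is represented by the marker nearest its physical
#' midpoint (the "middle marker"); the bin's `mid_bp`/`mid_cM` are that
#' marker's positions. Bins containing no marker are dropped.
#'
#' @param map genetic map as from [read_genetic_map()], sorted by
#'   (chrom, bp).
#' @param bin_size_bp bin width in bp.
#' @return a [bin_manifest()].
#' @export
make_bins <- function(map, bin_size_bp = 400000L) {
  if (bin_size_bp <= 0) stop_config("bin_size_bp must be positive")
  rows <- lapply(unique(map$chrom), function(ch) {
    mk <- map[map$chrom == ch, ]
    if (is.unsorted(mk$bp)) stop_data("genetic map not sorted by bp on chromosome ", ch)
    len <- max(mk$bp)
    start <- seq(1, len, by = bin_size_bp)
    end <- pmin(start + bin_size_bp - 1, len)
    centre <- (start + end) / 2
    # representative marker: nearest to the bin centre (ties -> left marker)
    idx <- findInterval(centre, mk$bp)
    lo <- pmax(idx, 1); hi <- pmin(idx + 1, nrow(mk))
    rep_idx <- ifelse(idx == 0, hi,
                      ifelse(abs(mk$bp[lo] - centre) <= abs(mk$bp[hi] - centre), lo, hi))
    keep <- mk$bp[rep_idx] >= start & mk$bp[rep_idx] <= end
    data.frame(bin_id = sprintf("%s_bin%05d", ch, seq_along(start)),
               chrom = ch, start_bp = start, end_bp = end,
               mid_bp = mk$bp[rep_idx], mid_cM = mk$cM[rep_idx])[keep, ]
  })
  bin_manifest(do.call(rbind, rows))
}

#' Drop bins near telomeres/centromeres
#'
#' Removes bins whose bp span intersects any annotated interval dilated by
#' `radius_bp` on each side (default 2 Mb, the exclusion radius used for
#' regions where local-ancestry inference is unreliable).
#'
#' @param manifest a [bin_manifest()].
#' @param annot exclusion intervals as from [read_bed_exclusions()]; may be
#'   empty.
#' @param radius_bp dilation radius in bp.
#' @return filtered [bin_manifest()], order preserved.
#' @export
apply_exclusions <- function(manifest, annot, radius_bp = 2000000) {
  if (is.null(annot) || nrow(annot) == 0) return(manifest)
  drop <- rep(FALSE, nrow(manifest))
  for (r in seq_len(nrow(annot))) {
    lo <- annot$start_bp[r] - radius_bp
    hi <- annot$end_bp[r] + radius_bp
    drop <- drop | (manifest$chrom == annot$chrom[r] &
                    manifest$start_bp <= hi & manifest$end_bp >= lo)
  }
  out <- manifest[!drop, ]
  attr(out, "n_excluded") <- sum(drop)
  bin_manifest(out)
}

#' Filter samples by genome-wide ancestry proportion
#'
#' Removes individuals whose genome-wide mean African proportion
#' (mean dosage / 2) is `<= low` or `>= high`; such near-unadmixed samples
#' carry no local-ancestry contrast.
#'
#' @param la a [local_ancestry()].
#' @param low,high exclusion bounds (boundaries themselves are excluded).
#' @return filtered [local_ancestry()] with attribute `n_removed`.
#' @export
filter_samples <- function(la, low = 0.05, high = 0.98) {
  prop <- rowMeans(la$dosage) / 2
  keep <- prop > low & prop < high
  if (!any(keep))
    stop_data("all ", length(keep), " samples removed by the ancestry-proportion filter")
  out <- local_ancestry(la$dosage[keep, , drop = FALSE], cohort = la$cohort)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Write a correlation or residual matrix as TSV
#'
#' Square matrix with bin ids as header and a leading `bin_id` column.
#'
#' @param x a `correlation_matrix` (its `beta`) or `residual_matrix`
#'   (its `beta_res`), or a plain matrix with dimnames.
#' @param path file path.
#' @return invisible path.
#' @export
write_matrix_tsv <- function(x, path) {
  m <- if (inherits(x, "correlation_matrix")) x$beta
       else if (inherits(x, "residual_matrix")) x$beta_res
       else as.matrix(x)
  ids <- if (inherits(x, c("correlation_matrix", "residual_matrix"))) x$bin_ids
         else colnames(m)
  df <- data.frame(bin_id = ids, m, check.names = FALSE)
  colnames(df) <- c("bin_id", ids)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
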