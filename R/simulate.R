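#' Configuration for the forward-time admixture simulator
#'
#' Describes a hybrid-isolation admixture scenario: a single admixture event
#' `t_generations` ago between an African-like source (initial proportion
#' `m_admixture`) and a European-like source, followed by random mating in a
#' closed population of constant size. Optionally, a two-locus epistatic
#' fitness scheme acts on offspring viability each generation.
#'
#' The genetic map inside the simulator is linear per chromosome: physical
#' position `bp` maps to `bp / length_bp * length_cM`.
#'
#' @param n_individuals number of diploid individuals (>= 2).
#' @param t_generations generations since admixture (>= 0).
#' @param m_admixture initial African ancestry proportion in `[0, 1]`.
#' @param chromosomes data.frame (or matrix) with columns `length_morgans`
#'   and `length_bp`, one row per chromosome.
#' @param bin_size_bp bin width in bp (default 400 kb, the bin width used for
#'   binned local-ancestry scans).
#' @param epistasis `NULL`, or `list(chrom =, locus_i_cM =, locus_j_cM =,
#'   s =)` placing a viability-epistasis pair on one chromosome with
#'   selection coefficient `s >= 0`.
#' @param seed integer seed; the whole simulation is reproducible given it.
#' @return object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(200, 8, 0.8, data.frame(length_morgans = 2, length_bp = 2e8))
sim_config <- function(n_individuals, t_generations, m_admixture, chromosomes,
                       bin_size_bp = 400000L, epistasis = NULL, seed = 1L) {
  chromosomes <- as.data.frame(chromosomes)
  if (!all(c("length_morgans", "length_bp") %in% names(chromosomes)))
    stop_config("chromosomes needs columns length_morgans and length_bp")
  if (n_individuals < 2) stop_config("n_individuals must be >= 2")
  if (t_generations < 0) stop_config("t_generations must be >= 0")
  if (m_admixture < 0 || m_admixture > 1) stop_config("m_admixture must be in [0, 1]")
  if (any(chromosomes$length_morgans <= 0) || any(chromosomes$length_bp <= 0))
    stop_config("chromosome lengths must be positive in both units")
  if (bin_size_bp <= 0) stop_config("bin_size_bp must be positive")
  if (!is.null(epistasis)) {
    need <- c("chrom", "locus_i_cM", "locus_j_cM", "s")
    if (!all(need %in% names(epistasis))) stop_config("epistasis needs fields ", paste(need, collapse = ", "))
    if (epistasis$s < 0) stop_config("selection coefficient s must be >= 0")
    ch <- epistasis$chrom
    if (ch < 1 || ch > nrow(chromosomes)) stop_config("epistasis chromosome out of range")
    span_cM <- chromosomes$length_morgans[ch] * 100
    if (any(c(epistasis$locus_i_cM, epistasis$locus_j_cM) < 0) ||
        any(c(epistasis$locus_i_cM, epistasis$locus_j_cM) > span_cM))
      stop_config("epistasis loci outside the chromosome span (0-", span_cM, " cM)")
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 t_generations = as.integer(t_generations),
                 m_admixture = m_admixture, chromosomes = chromosomes,
                 bin_size_bp = as.integer(bin_size_bp), epistasis = epistasis,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a two-way admixed population with optional epistatic selection
#'
#' Forward-time simulation under the hybrid-isolation model. Generation 0
#' haplotypes are single-ancestry (African with probability `m_admixture`).
#' Each later generation, every offspring draws two distinct parents
#' (uniformly when `s = 0`); each transmitted chromosome recombines with a
#' Poisson(length in Morgans) number of crossovers at uniform genetic-map
#' positions (Haldane's model, no interference). With epistasis, fitness
#' `w = 1 + s * I(dosage_i == dosage_j)` is evaluated on the offspring's
#' diploid African-ancestry dosages at the two loci and the offspring is
#' accepted by rejection sampling with probability `w / (1 + s)`.
#'
#' @param config a [sim_config()].
#' @return list with elements
#'   \item{ancestry}{[local_ancestry()] of diploid African dosages (0/1/2) at
#'     bin midpoints, individuals x bins;}
#'   \item{manifest}{[bin_manifest()] of the bins;}
#'   \item{tracts}{data.frame of final-generation ancestry tracts
#'     (`hap`, `chrom`, `start_cM`, `end_cM`, `ancestry` in \{"AFR","EUR"\});
#'     haplotypes `2k - 1`, `2k` belong to individual `k`.}
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  manifest <- sim_manifest(config)
  bin_pos_M <- lapply(split(manifest, manifest$chrom),
                      function(d) d$mid_cM / 100)
  bin_pos_M <- bin_pos_M[order(as.integer(names(bin_pos_M)))]
  epi <- config$epistasis
  out <- with_seed(config$seed,
    simulate_tracts_cpp(config$n_individuals, config$t_generations,
                        config$m_admixture, config$chromosomes$length_morgans,
                        bin_pos_M,
                        if (is.null(epi)) -1L else as.integer(epi$chrom) - 1L,
                        if (is.null(epi)) 0 else epi$locus_i_cM / 100,
                        if (is.null(epi)) 0 else epi$locus_j_cM / 100,
                        if (is.null(epi)) 0 else epi$s))
  dosage <- out$dosage
  rownames(dosage) <- sprintf("ind%05d", seq_len(config$n_individuals))
  colnames(dosage) <- manifest$bin_id
  tracts <- data.frame(hap = out$tract_hap, chrom = out$tract_chrom,
                       start_cM = out$tract_start_M * 100,
                       end_cM = out$tract_end_M * 100,
                       ancestry = ifelse(out$tract_anc == 1L, "AFR", "EUR"))
  list(ancestry = local_ancestry(dosage, cohort = "simulated"),
       manifest = manifest, tracts = tracts)
}

# bin manifest implied by a simulator config: fixed-width bp bins, linear map
sim_manifest <- function(config) {
  rows <- lapply(seq_len(nrow(config$chromosomes)), function(c) {
    len_bp <- config$chromosomes$length_bp[c]
    len_cM <- config$chromosomes$length_morgans[c] * 100
    start <- seq(1, len_bp, by = config$bin_size_bp)
    end <- pmin(start + config$bin_size_bp - 1, len_bp)
    mid_bp <- floor((start + end) / 2)
    data.frame(bin_id = sprintf("chr%d_bin%05d", c, seq_along(start)),
               chrom = c, start_bp = start, end_bp = end, mid_bp = mid_bp,
               mid_cM = mid_bp / len_bp * len_cM)
  })
  bin_manifest(do.call(rbind, rows))
}

#' Expected null ancestry correlation under the hybrid-isolation model
#'
#' The admixture-LD decay model `D = D0 (1 - d)^t`, with `d` the genetic
#' distance acting as a per-generation recombination fraction; at short
#' distances this is close to `exp(-t d)`. Used as the analytic reference for
#' the simulator's ancestry-correlation decay (which is exact only to first
#' order in `d`, since the simulator's per-meiosis recombination fraction
#' follows Haldane's map function).
#'
#' @param t generations since admixture (>= 0).
#' @param d_cM genetic distance in centiMorgans (>= 0; vectorised).
#' @return `(1 - d)^t` with `d` in Morgans, floored at 0 for `d >= 1` Morgan.
#' @export
#' @examples
#' expected_null_correlation(8, 10)  # 0.9^8
expected_null_correlation <- function(t, d_cM) {
  if (any(t < 0) || any(d_cM < 0)) stop_config("t and d must be non-negative")
  dM <- d_cM / 100
  ifelse(dM < 1, (1 - dM)^t, 0)
}

#' Write simulator outputs as TSV files
#'
#' Writes `<prefix>.ancestry.tsv`, `<prefix>.manifest.tsv` and (optionally)
#' `<prefix>.tracts.tsv`.
#'
#' @param sim result of [simulate_population()].
#' @param prefix output path prefix.
#' @param tracts whether to write the tract file.
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, prefix, tracts = TRUE) {
  paths <- c(ancestry = paste0(prefix, ".ancestry.tsv"),
             manifest = paste0(prefix, ".manifest.tsv"))
  write_ancestry(sim$ancestry, paths["ancestry"])
  write_manifest(sim$manifest, paths["manifest"])
  if (tracts) {
    paths <- c(paths, tracts = paste0(prefix, ".tracts.tsv"))
    data.table::fwrite(sim$tracts, paths["tracts"], sep = "\t")
  }
  invisible(paths)
}
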