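make_rmx <- function(beta_res, d_cM, beta = NULL) {
  M <- nrow(beta_res)
  ids <- sprintf("b%02d", seq_len(M))
  if (is.null(beta)) beta <- beta_res
  structure(list(chrom = "1", bin_ids = ids, beta = beta, beta_res = beta_res,
                 res_dir = beta_res, d_cM = d_cM, mid_bp = seq_len(M) * 1e6,
                 n_samples = 100, n_masked = 0),
            class = "residual_matrix")
}

scale_of <- function(sigma) structure(list(sigma_hat = sigma, n_pairs_used = 10,
                                           subsample_seed = NULL),
                                      class = "null_scale")

test_that("the Z-test matches the normal CDF and handles the null point", {
  br <- matrix(0, 3, 3)
  br[1, 2] <- br[2, 1] <- 0
  br[1, 3] <- br[3, 1] <- 0.0195996398454005 / 2
  br[2, 3] <- br[3, 2] <- -0.03
  d <- abs(outer(1:3, 1:3, "-")) * 30
  sc <- z_test(make_rmx(br, d), scale_of(0.005))
  p12 <- sc[sc$bin_i == "b01" & sc$bin_j == "b02", ]
  expect_equal(p12$z, 0); expect_equal(p12$p, 1)
  p13 <- sc[sc$bin_i == "b01" & sc$bin_j == "b03", ]
  expect_equal(p13$z, 1.95996398454005, tolerance = 1e-9)
  expect_equal(p13$p, 0.05, tolerance = 1e-6)
  # grid of arbitrary (beta_res, sigma): P matches an independent CDF evaluation
  for (b in c(-0.02, 0.001, 0.013)) for (s in c(0.004, 0.02)) {
    br2 <- matrix(c(0, b, b, 0), 2)
    sc2 <- z_test(make_rmx(br2, matrix(c(0, 10, 10, 0), 2)), scale_of(s))
    expect_lt(abs(sc2$p - 2 * (1 - pnorm(abs(b / s)))), 1e-10)
  }
  expect_error(z_test(make_rmx(br, d), scale_of(0)), "positive")
})

test_that("effective bin counts reproduce hand eigen-decompositions", {
  expect_equal(effective_bins(diag(8)), 8L)
  expect_equal(effective_bins(matrix(1, 6, 6)), 1L)
  # two perfect pairs: eigenvalues 2, 2, 0, 0 -> k = 2
  b <- diag(4); b[1, 2] <- b[2, 1] <- 1; b[3, 4] <- b[4, 3] <- 1
  expect_equal(effective_bins(b), 2L)
  expect_error(effective_bins(matrix(c(1, 0.5, 0.2, 1), 2)), "symmetric")
})

test_that("total independent tests equals brute-force pair enumeration", {
  expect_equal(total_independent_tests(3), 3)
  expect_equal(total_independent_tests(c(2, 2)), 2)
  set.seed(3)
  k <- sample(1:40, 10)
  brute <- sum(vapply(k, function(ki) nrow(t(combn(ki, 2))), 0))
  expect_equal(total_independent_tests(k), brute)
  expect_error(total_independent_tests(c(3, 0)), ">= 1")
})

test_that("Bonferroni thresholds include the genome-wide scan level", {
  expect_equal(signif(bonferroni_threshold(61616), 3), 8.11e-7)
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(bonferroni_threshold(10), 0.005)
})

test_that("the distance filter is strict below the bound and keeps pairs for audit", {
  br <- matrix(0.01, 3, 3); diag(br) <- 0
  d <- matrix(c(0, 49.9, 50, 49.9, 0, 80, 50, 80, 0), 3)
  sc <- distance_filter(z_test(make_rmx(br, d), scale_of(0.01)))
  expect_equal(nrow(sc), 3)  # nothing dropped
  expect_false(sc$passes_distance_filter[sc$d_cM == 49.9])
  expect_true(all(sc$passes_distance_filter[sc$d_cM >= 50]))
  sc0 <- distance_filter(sc, min_cM = 0)
  expect_true(all(sc0$passes_distance_filter))
})

test_that("significance declaration combines the p threshold and distance flag", {
  br <- matrix(0, 4, 4)
  br[1, 3] <- br[3, 1] <- 0.08   # far pair, strong
  br[1, 2] <- br[2, 1] <- 0.08   # near pair, strong
  br[2, 4] <- br[4, 2] <- 0.001  # far pair, weak
  d <- abs(outer(c(0, 10, 60, 80), c(0, 10, 60, 80), "-"))
  sc <- declare_significant(distance_filter(z_test(make_rmx(br, d), scale_of(0.01))), 1e-4)
  sig <- sc[sc$significant, ]
  expect_equal(nrow(sig), 1)
  expect_equal(c(sig$bin_i, sig$bin_j), c("b01", "b03"))
  expect_true(all(sc$significant == (sc$passes_distance_filter & sc$p < 1e-4)))
})

test_that("region merging matches a brute-force union-find oracle", {
  toy_man <- function(M) bin_manifest(data.frame(
    bin_id = sprintf("b%02d", 1:M), chrom = "1",
    start_bp = (1:M - 1) * 4e5 + 1, end_bp = (1:M) * 4e5,
    mid_bp = (1:M - 1) * 4e5 + 2e5, mid_cM = (1:M) * 0.4))
  man <- toy_man(30)
  mk_scan <- function(pairs) {
    data.frame(chrom = "1", bin_i = sprintf("b%02d", pairs[, 1]),
               bin_j = sprintf("b%02d", pairs[, 2]),
               mid_bp_i = 0, mid_bp_j = 0, d_cM = 100, beta = 0, beta_res = 0,
               z = 9, p = 1e-12, passes_distance_filter = TRUE, significant = TRUE)
  }
  # single pair -> one region pair of single bins
  rp <- merge_region_pairs(mk_scan(cbind(3, 20)), man)
  expect_equal(nrow(rp), 1)
  expect_equal(rp$region1_start_bp, man$start_bp[3])
  expect_equal(rp$region2_end_bp, man$end_bp[20])

  # two pairs sharing bin_i with adjacent bin_j -> merged
  rp2 <- merge_region_pairs(mk_scan(rbind(c(3, 20), c(3, 21))), man)
  expect_equal(nrow(rp2), 1)
  expect_equal(rp2$n_pairs, 2)

  # random sparse masks vs union-find over the stated adjacency
  for (seed in 1:4) {
    set.seed(seed)
    pr <- unique(t(replicate(12, sort(sample(30, 2)))))
    rp3 <- merge_region_pairs(mk_scan(pr), man, gap_bins = 1)
    # union-find oracle
    parent <- seq_len(nrow(pr))
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (a in seq_len(nrow(pr))) for (b in seq_len(nrow(pr))) {
      if (abs(pr[a, 1] - pr[b, 1]) <= 1 && abs(pr[a, 2] - pr[b, 2]) <= 1) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[ra] <- rb
      }
    }
    roots <- vapply(seq_len(nrow(pr)), find, 0L)
    expect_equal(nrow(rp3), length(unique(roots)))
    oracle_sizes <- sort(as.vector(table(roots)))
    expect_equal(sort(rp3$n_pairs), oracle_sizes)
  }

  # empty input -> empty output
  empty <- mk_scan(cbind(3, 20)); empty$significant <- FALSE
  expect_equal(nrow(merge_region_pairs(empty, man)), 0)
})

test_that("heatmap capping follows the -log10 convention", {
  expect_equal(neglog10_capped(c(1e-9, 1e-3, 0.5)), c(6, 3, -log10(0.5)))
})
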