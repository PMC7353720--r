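test_that("weighted-Z meta matches the scalar formula and closed forms", {
  # single cohort: identity
  expect_equal(weighted_z_meta(matrix(1.7), 500)$z_meta, 1.7)
  # equal-n cohorts with opposite Z cancel
  expect_equal(weighted_z_meta(matrix(c(2.2, -2.2), 1), c(1000, 1000))$z_meta, 0)
  # K identical cohorts with equal n: z_meta = sqrt(K) * z
  expect_equal(weighted_z_meta(matrix(c(1.3, 1.3, 1.3), 1), rep(400, 3))$z_meta,
               sqrt(3) * 1.3, tolerance = 1e-12)
  # three cohorts at realistic sample sizes vs independent scalar evaluation
  n <- c(6238, 1864, 8150)
  z <- c(1.1, -0.4, 2.3)
  manual <- (sqrt(n[1]) * z[1] + sqrt(n[2]) * z[2] + sqrt(n[3]) * z[3]) /
    sqrt(n[1] + n[2] + n[3])
  got <- weighted_z_meta(matrix(z, 1), n)
  expect_equal(got$z_meta, manual, tolerance = 1e-12)
  expect_equal(got$p_meta, 2 * (1 - pnorm(abs(manual))), tolerance = 1e-12)
})

test_that("Cochran's Q follows the hand formula and flags degenerate input", {
  expect_equal(cochran_q(matrix(c(0.02, 0.02, 0.02), 1), c(1e-4, 1e-4, 1e-4))$q, 0)
  expect_equal(cochran_q(matrix(c(0.02, 0.02, 0.02), 1), c(1e-4, 1e-4, 1e-4))$q_p, 1)
  # two cohorts, equal variances v: Q = (b1 - b2)^2 / (2 v)
  b1 <- 0.03; b2 <- -0.01; v <- 2e-4
  expect_equal(cochran_q(matrix(c(b1, b2), 1), c(v, v))$q, (b1 - b2)^2 / (2 * v),
               tolerance = 1e-12)
  expect_error(cochran_q(matrix(0.1), 1e-4), ">= 2")
  expect_error(cochran_q(matrix(c(0.1, 0.2), 1), c(0, 1e-4)), "positive")
})

test_that("Q p-values are roughly uniform across independent null cohorts", {
  set.seed(91)
  K <- 3; v <- 4e-4; npair <- 4000
  b <- matrix(rnorm(npair * K, 0, sqrt(v)), npair)
  q <- cochran_q(b, rep(v, K))
  ks <- suppressWarnings(ks.test(q$q_p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(q$q_p > 0.05), 0.92)
})

test_that("genomic-control lambda is calibrated and matches the median formula", {
  z <- qnorm(seq(0.0005, 0.9995, length.out = 2000))
  expect_equal(genomic_control_lambda(z), 1, tolerance = 0.01)
  expect_equal(genomic_control_lambda(rep(0, 5)), 0)
  set.seed(12); z2 <- rnorm(501, 0, 1.4)
  expect_equal(genomic_control_lambda(z2),
               median(z2^2) / qchisq(0.5, 1), tolerance = 1e-12)
})

test_that("cohort Z correlation is 1 with itself, ~0 under independence, > 0 with shared signal", {
  set.seed(42)
  z <- rnorm(3000)
  expect_equal(cohort_z_correlation(cbind(a = z, b = z))$r, 1)
  indep <- cbind(a = rnorm(3000), b = rnorm(3000))
  expect_lt(abs(cohort_z_correlation(indep)$r), 3 / sqrt(3000))
  shared <- rnorm(3000, 0, 0.6)
  dep <- cbind(a = shared + rnorm(3000, 0, 0.8), b = shared + rnorm(3000, 0, 0.8))
  expect_gt(cohort_z_correlation(dep)$r, 0.2)
  expect_error(cohort_z_correlation(indep[1, , drop = FALSE]), ">= 2")
})

test_that("skewness uses the adjusted Fisher-Pearson estimator", {
  set.seed(8)
  x <- rnorm(20000)
  expect_lt(abs(residual_skewness(x)), 0.05)
  # {0, 0, 1} scaled: hand formula
  y <- c(0, 0, 1) * 3
  n <- 3; m <- mean(y)
  g1 <- mean((y - m)^3) / mean((y - m)^2)^1.5
  expect_equal(residual_skewness(y), g1 * sqrt(n * (n - 1)) / (n - 2), tolerance = 1e-12)
  expect_gt(residual_skewness(rexp(5000)), 0.5)
  expect_error(residual_skewness(rep(1, 10)), "zero-variance")
  expect_error(residual_skewness(c(1, 2)), ">= 3")
})

test_that("run_meta aligns cohorts, computes diagnostics, and rejects grid mismatches", {
  toy <- toy_ancestry(n = 400, bins = 12, chroms = 2, seed = 31)
  cms <- within_chromosome_correlations(toy$la, toy$manifest)
  scale <- estimate_null_scale(toy$la, toy$manifest)
  mk_scan <- function(seed) {
    t2 <- toy_ancestry(n = 400, bins = 12, chroms = 2, seed = seed)
    cms <- within_chromosome_correlations(t2$la, t2$manifest)
    sc <- do.call(rbind, lapply(cms, function(cm)
      z_test(residual_correlations(cm, fit_chromosome_decay(cm)), scale)))
    rownames(sc) <- NULL
    class(sc) <- c("scan_result", "data.frame")
    distance_filter(sc, min_cM = 2)
  }
  scans <- list(cohortA = mk_scan(31), cohortB = mk_scan(77), cohortC = mk_scan(78))
  meta <- run_meta(scans, c(6238, 1864, 8150), sigma_by_cohort = rep(scale$sigma_hat, 3))
  expect_s3_class(meta, "meta_result")
  expect_equal(nrow(meta$pairs), nrow(scans[[1]]))
  # meta Z matches the scalar formula on a spot-checked pair
  r <- 7
  manual <- weighted_z_meta(matrix(c(scans[[1]]$z[r], scans[[2]]$z[r], scans[[3]]$z[r]), 1),
                            c(6238, 1864, 8150))
  expect_equal(meta$pairs$z_meta[r], manual$z_meta, tolerance = 1e-12)
  expect_length(meta$skewness, 3)
  expect_equal(nrow(meta$z_correlations), 3)

  # meta of one cohort reproduces that cohort's scan
  m1 <- run_meta(scans[1], 6238)
  expect_equal(m1$pairs$z_meta, scans[[1]]$z, tolerance = 1e-12)
  # meta of a cohort with itself at equal n: z_meta = sqrt(2) z
  m2 <- run_meta(list(a = scans[[1]], b = scans[[1]]), c(500, 500),
                 sigma_by_cohort = rep(scale$sigma_hat, 2))
  expect_equal(m2$pairs$z_meta, sqrt(2) * scans[[1]]$z, tolerance = 1e-12)

  bad <- scans
  bad[[2]] <- bad[[2]][-3, ]
  expect_error(run_meta(bad, c(1, 2, 3), rep(0.01, 3)), "shared bin grid")
})

test_that("qq_data returns matched expected/observed quantiles", {
  p <- c(0.5, 0.01, 0.2)
  qd <- qq_data(p)
  expect_equal(qd$observed, -log10(sort(p)))
  expect_equal(qd$expected, -log10((1:3 - 0.5) / 3))
})
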