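fake_counts <- function(total, feature = "t1", pool = "Pool1", age = 4,
                        meth = NULL, pos = seq_along(total)) {
  if (is.null(meth)) meth <- pmin(total, 1L)
  data.frame(chrom = "chr1", pos = pos, feature = feature,
             pool_id = pool, pool_age = age, meth_reads = meth,
             total_reads = total, stringsAsFactors = FALSE)
}

test_that("coverage filter applies the >= 25 boundary and is idempotent", {
  cnt <- fake_counts(c(24, 25, 26, 10, 100))
  kept <- coverage_filter(cnt, 25)
  expect_equal(kept$total_reads, c(25, 26, 100))
  expect_equal(coverage_filter(kept, 25), kept)
  # monotone: raising the threshold never adds records
  expect_true(nrow(coverage_filter(cnt, 30)) <= nrow(kept))
})

test_that("RRBS preset drops whole features at or below 10 data points", {
  # feature with exactly 10 retained CpGs is dropped (strict > 10)
  cnt10 <- fake_counts(rep(60, 10), feature = "t10")
  cnt11 <- fake_counts(rep(60, 11), feature = "t11")
  both <- rbind(cnt10, cnt11)
  kept <- rrbs_filter(both, min_reads = 50, min_sites = 10)
  expect_false("t10" %in% kept$feature)
  expect_true("t11" %in% kept$feature)
  # strict > 50 reads: a 50-read record does not count
  cnt_edge <- fake_counts(c(rep(51, 11), 50), feature = "te")
  kept_edge <- rrbs_filter(cnt_edge, 50, 10)
  expect_equal(nrow(kept_edge), 11L)
})

test_that("Bismark coverage files read back as counts", {
  path <- withr::local_tempfile(fileext = ".cov")
  writeLines(c("chr1\t101\t101\t50\t30\t30", "chr1\t150\t150\t10\t5\t45"),
             path)
  cnt <- read_bismark_cov(path, pool_id = "Pool1", pool_age = 4)
  expect_equal(cnt$pos, c(101, 150))
  expect_equal(cnt$meth_reads, c(30, 5))
  expect_equal(cnt$total_reads, c(60, 50))
  expect_equal(cnt$pool_id, c("Pool1", "Pool1"))
})

test_that("CpG-to-feature assignment respects half-open BED bounds", {
  feats <- data.frame(chrom = "chr1", start = 100, end = 180, name = "t1",
                      stringsAsFactors = FALSE)
  cnt <- fake_counts(rep(30, 4), pos = c(100, 101, 180, 181))
  cnt$feature <- NULL
  got <- assign_cpgs_to_features(cnt, feats)
  expect_equal(got$pos, c(101, 180))
})

test_that("pairwise region test: hand-computed delta and degenerate variance", {
  # 3 CpGs, one pool per group, differences exactly 0.03 everywhere
  a <- fake_counts(rep(100, 3), pool = "PoolA", meth = c(2, 3, 4))
  b <- fake_counts(rep(100, 3), pool = "PoolB", meth = c(5, 6, 7))
  res <- pairwise_region_test(rbind(a, b), "PoolA", "PoolB")
  expect_equal(res$delta, 0.03, tolerance = 1e-12)
  expect_equal(res$flag, "zero_variance")
  expect_equal(res$p_paired, 0)
  # identical profiles: delta 0, degenerate p = 1
  res2 <- pairwise_region_test(rbind(a, transform(a, pool_id = "PoolB")),
                               "PoolA", "PoolB")
  expect_equal(res2$delta, 0)
  expect_equal(res2$p_paired, 1)
  # single CpG returns the per-CpG route only
  a1 <- fake_counts(100, pool = "PoolA", meth = 10)
  a2 <- fake_counts(100, pool = "PoolA2", meth = 12)
  b1 <- fake_counts(100, pool = "PoolB", meth = 30)
  b2 <- fake_counts(100, pool = "PoolB2", meth = 32)
  res3 <- pairwise_region_test(rbind(a1, a2, b1, b2),
                               c("PoolA", "PoolA2"), c("PoolB", "PoolB2"))
  expect_equal(res3$flag, "single_cpg")
  expect_true(is.na(res3$p_paired))
  expect_false(is.na(res3$combined_p))
  # no shared CpGs is an error
  odd <- fake_counts(100, pool = "PoolB", pos = 99)
  expect_error(pairwise_region_test(rbind(a, odd), "PoolA", "PoolB"),
               "shared CpGs|pool")
})

test_that("planted 3.7% pooled delta is recovered within 0.01", {
  des <- pool_design_default()
  sites <- data.frame(feature = "t", chrom = "chr1", pos = 10 * (1:6),
                      stringsAsFactors = FALSE)
  n_ok <- 0L
  n_rep <- 200L
  for (r in seq_len(n_rep)) {
    cnt <- simulate_pooled_bis(des, sites, baseline_meth = 0.02,
                               slope_per_year = 5e-4, affected = "t",
                               coverage_mean = 700, seed = 5000 + r)
    res <- pairwise_region_test(coverage_filter(cnt),
                                c("Pool1", "Pool2"), c("Pool7", "Pool8"))
    truth <- 5e-4 * (mean(c(77.96, 77.22)) - mean(c(4.07, 4.09)))
    if (abs(res$delta - truth) <= 0.01) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok, 0.95 * n_rep)
})

test_that("Fisher combination matches the chi-squared tail oracle", {
  expect_equal(combine_pvalues(c(1, 1, 1))$p_value, 1)
  expect_equal(combine_pvalues(0.05)$p_value, 0.05, tolerance = 1e-12)
  got <- combine_pvalues(c(0.01, 0.04))
  X <- -2 * (log(0.01) + log(0.04))
  expect_equal(got$statistic, X)
  expect_equal(got$p_value, pchisq(X, 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(got$p_value, 4), 0.0035, tolerance = 1e-3)
  expect_error(combine_pvalues(numeric()), "no p-values")
  expect_warning(z <- combine_pvalues(c(0, 0.5)), "clipped")
  expect_true(z$p_value > 0)
})

test_that("combined p of iid uniforms is uniform", {
  set.seed(303)
  ps <- vapply(1:2000, function(i) {
    combine_pvalues(runif(4))$p_value
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Brown adjustment widens the reference for correlated tests", {
  set.seed(404)
  n <- 40
  shared <- rnorm(n)
  data <- rbind(shared + rnorm(n, 0, 0.2), shared + rnorm(n, 0, 0.2),
                shared + rnorm(n, 0, 0.2))
  ps <- c(0.04, 0.05, 0.03)
  fisher <- combine_pvalues(ps)$p_value
  brown <- combine_pvalues(ps, method = "brown", data = data)$p_value
  expect_gt(brown, fisher)  # dependence discount
  expect_equal(combine_pvalues(ps, method = "brown",
                               data = diag(3) %*% matrix(rnorm(120), 3))$method,
               "brown")
})

test_that("rank-sum comparison matches exhaustive relabelling", {
  r <- rank_sum_compare(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(r$p_value, 1 / 20)
  expect_equal(r$W, 0)
  set.seed(505)
  for (rep in 1:25) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    vals <- sample(1000, na + nb)  # distinct => tie-free exact test
    a <- vals[1:na]; b <- vals[-(1:na)]
    alt <- sample(c("greater", "less", "two.sided"), 1)
    got <- rank_sum_compare(a, b, alternative = alt)
    expect_equal(got$p_value, oracle_ranksum(a, b, alt), tolerance = 1e-12)
  }
})

test_that("rank-sum shift estimate and degenerate handling", {
  a <- c(3, 1, 2)
  r <- rank_sum_compare(a, a)
  expect_equal(r$estimate, 0, tolerance = 1e-9)
  same <- rank_sum_compare(rep(2, 4), rep(2, 5))
  expect_equal(same$p_value, 1)
  expect_equal(same$estimate, 0)
  expect_error(rank_sum_compare(numeric(), 1:3), "non-empty")
  # one-sided CI is half-open on the alternative side
  set.seed(9)
  g <- rank_sum_compare(rnorm(20, 1), rnorm(20, 0), alternative = "greater")
  expect_equal(g$conf_int[2], Inf)
})

test_that("pooled age regression matches OLS in both orientations", {
  ages <- pool_design_default()$mean_age
  meth <- 0.02 + 5e-4 * ages
  r <- suppressWarnings(fit_pool_age_regression(meth, ages))
  expect_equal(r$slope_meth_per_year, 5e-4, tolerance = 1e-10)
  expect_lt(r$p_value, 1e-6)
  const <- fit_pool_age_regression(rep(0.02, 8), ages)
  expect_equal(const$slope_meth_per_year, 0)
  expect_equal(const$p_value, 1)
  expect_error(fit_pool_age_regression(c(0.1, 0.2), c(4, 28)), ">= 3")
  set.seed(66)
  noisy <- meth + rnorm(8, 0, 0.003)
  got <- fit_pool_age_regression(noisy, ages)
  want <- oracle_ols(noisy, cbind(1, ages))
  expect_equal(got$slope_meth_per_year, want$slope, tolerance = 1e-10)
  expect_equal(got$p_value, unname(want$p), tolerance = 1e-10)
})

test_that("region delta is invariant to CpG ordering", {
  a <- fake_counts(rep(100, 4), pool = "PoolA", meth = c(2, 9, 4, 7))
  b <- fake_counts(rep(100, 4), pool = "PoolB", meth = c(5, 6, 7, 1))
  fwd <- pairwise_region_test(rbind(a, b), "PoolA", "PoolB")
  perm <- sample(1:4)
  shuffled <- pairwise_region_test(rbind(a[perm, ], b[rev(perm), ]),
                                   "PoolA", "PoolB")
  expect_equal(fwd$delta, shuffled$delta, tolerance = 1e-12)
})
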