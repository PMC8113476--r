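make_samples <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    sample_id = sprintf("S%03d", 1:n),
    participant_id = sprintf("P%03d", 1:n),
    age = runif(n, 16, 82),
    batch = sample(c("b1", "b2", "b3"), n, replace = TRUE),
    lymphocytes = pmax(rnorm(n, 2, 0.5), 0),
    monocytes = pmax(rnorm(n, 0.5, 0.15), 0),
    neutrophils = pmax(rnorm(n, 4, 1), 0),
    eosinophils = pmax(rnorm(n, 0.2, 0.1), 0),
    stringsAsFactors = FALSE
  )
}

test_that("model specs carry the documented covariate sets", {
  expect_equal(age_model_spec(1)$covariates, character())
  expect_equal(age_model_spec(2)$covariates, "batch")
  expect_setequal(age_model_spec(3)$covariates,
                  c("lymphocytes", "monocytes", "neutrophils", "eosinophils"))
  expect_setequal(age_model_spec(4)$covariates,
                  c("batch", "lymphocytes", "monocytes", "neutrophils",
                    "eosinophils"))
  expect_true("participant_id" %in% age_model_spec("longitudinal")$covariates)
  expect_error(age_model_spec(9), "unknown")
})

test_that("a perfect linear age effect is recovered exactly", {
  s <- make_samples(50)
  r <- fit_age_model(0.1 * s$age, s, age_model_spec(1))
  expect_equal(r$slope, 0.1, tolerance = 1e-10)
  expect_lt(r$p_value, 1e-12)
})

test_that("OLS slope, se and partial-F p match the normal-equations oracle", {
  set.seed(33)
  for (rep in 1:20) {
    s <- make_samples(60, seed = rep)
    meth <- rnorm(60, 5, 1) + 0.01 * s$age
    spec <- age_model_spec(4)
    got <- fit_age_model(meth, s, spec)
    X <- cbind(1, model.matrix(~ batch, s)[, -1],
               s$lymphocytes, s$monocytes, s$neutrophils, s$eosinophils,
               s$age)
    want <- oracle_ols(meth, X)
    expect_equal(got$slope, want$slope, tolerance = 1e-10)
    expect_equal(got$se, want$se, tolerance = 1e-10)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
  }
})

test_that("model-1 partial F equals the simple-regression F-test", {
  set.seed(2)
  s <- make_samples(80)
  meth <- rnorm(80) + 0.02 * s$age
  got <- fit_age_model(meth, s, age_model_spec(1))
  lmfit <- lm(meth ~ s$age)
  fs <- summary(lmfit)$fstatistic
  expect_equal(got$p_value, pf(fs[1], fs[2], fs[3], lower.tail = FALSE),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(got$slope, unname(coef(lmfit)[2]), tolerance = 1e-12)
})

test_that("null p-values are uniform", {
  set.seed(4)
  s <- make_samples(200)
  ps <- vapply(1:1000, function(i) {
    fit_age_model(rnorm(200), s, age_model_spec(1))$p_value
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("degenerate and ill-posed inputs are flagged or refused", {
  s <- make_samples(40)
  expect_warning(r <- fit_age_model(rep(2, 40), s, age_model_spec(1)),
                 "zero-variance")
  expect_equal(r$p_value, 1)
  expect_equal(r$slope, 0)
  expect_equal(r$flag, "zero_variance")
  s2 <- make_samples(40)
  s2$age <- 50
  expect_warning(r2 <- fit_age_model(rnorm(40), s2, age_model_spec(1)),
                 "zero-variance")
  expect_equal(r2$p_value, 1)
  # collinear covariate named in the error
  s3 <- make_samples(40)
  s3$monocytes <- s3$lymphocytes * 2
  expect_error(fit_age_model(rnorm(40), s3, age_model_spec(3)), "monocytes")
  # too few samples
  expect_error(fit_age_model(rnorm(3), make_samples(3), age_model_spec(1)),
               "too few")
})

test_that("an orthogonal covariate leaves the slope unchanged", {
  set.seed(8)
  n <- 64
  s <- make_samples(n)
  # Hadamard-style contrasts: age and all four cell counts are exactly
  # mutually orthogonal, so adding them must not move the age slope
  s$age <- rep(c(-1, 1), n / 2) * 10 + 50
  s$lymphocytes <- rep(c(1, 1, -1, -1), n / 4) + 2
  s$monocytes <- rep(rep(c(1, -1), each = 4), n / 8) * 0.2 + 0.5
  s$neutrophils <- rep(rep(c(1, -1), each = 8), n / 16) + 4
  s$eosinophils <- rep(rep(c(1, -1), each = 16), n / 32) * 0.1 + 0.2
  meth <- rnorm(n) + 0.05 * s$age
  r1 <- fit_age_model(meth, s, age_model_spec(1))
  s_cov <- s
  r3 <- fit_age_model(meth, s_cov, age_model_spec(3))
  expect_equal(r1$slope, r3$slope, tolerance = 1e-8)
})

test_that("fit_all_windows equals looping fit_age_model and keeps order", {
  sim <- small_sim(seed = 3, n_samples = 80, n_trna = 5, chrom_len = 5e4)
  spec <- age_model_spec(4)
  batch <- fit_all_windows(sim$scores, sim$samples, spec)
  expect_equal(nrow(batch), nrow(sim$scores))
  expect_equal(batch$window, rownames(sim$scores))
  for (i in c(1, 17, nrow(sim$scores))) {
    single <- fit_age_model(sim$scores[i, ], sim$samples, spec)
    expect_equal(batch$slope[i], single$slope, tolerance = 1e-10)
    expect_equal(batch$p_value[i], single$p_value, tolerance = 1e-10)
  }
  empty <- fit_all_windows(sim$scores[0, , drop = FALSE], sim$samples, spec)
  expect_equal(nrow(empty), 0L)
  # degenerate window flagged, not dropped
  scores2 <- sim$scores[1:3, , drop = FALSE]
  scores2[2, ] <- 7
  batch2 <- fit_all_windows(scores2, sim$samples, spec)
  expect_equal(batch2$flag[2], "zero_variance")
  expect_equal(batch2$p_value[2], 1)
  expect_equal(nrow(batch2), 3L)
})

test_that("both model directions agree on association significance", {
  set.seed(12)
  s <- make_samples(150)
  meth <- rnorm(150, 5, 0.5) + 0.02 * s$age
  fwd <- fit_age_model(meth, s, age_model_spec(1, "meth_response"))
  rev <- fit_age_model(meth, s, age_model_spec(1, "age_response"))
  expect_equal(fwd$p_value, rev$p_value, tolerance = 1e-10)
  expect_gt(fwd$slope, 0)
  expect_gt(rev$slope, 0)
})

test_that("longitudinal filter keeps only well-spaced revisits", {
  sim <- small_sim(seed = 23, n_samples = 300, longitudinal_fraction = 0.3)
  fit <- fit_longitudinal(sim$scores[1:10, , drop = FALSE], sim$samples,
                          min_gap_years = 5)
  spans <- tapply(fit$samples_used$age, fit$samples_used$participant_id,
                  function(a) diff(range(a)))
  expect_true(all(spans >= 5))
  expect_equal(nrow(fit$results), 10L)
  # participants with a 4-year gap are excluded
  s <- sim$samples[sim$samples$visit == 1, ][1:20, ]
  s2 <- s[1, ]; s2$age <- s2$age <- s$age[1] + 4; s2$visit <- 2L
  s2$sample_id <- "S_extra"
  samples44 <- rbind(s, s2)
  scores44 <- matrix(rnorm(21), nrow = 1,
                     dimnames = list("w", samples44$sample_id))
  expect_error(fit_longitudinal(scores44, samples44), "qualifying")
})

test_that("longitudinal models recover a planted within-person slope", {
  set.seed(55)
  n_part <- 60
  base <- rnorm(n_part, 5, 2)  # large between-person differences
  age1 <- runif(n_part, 20, 60)
  gap <- runif(n_part, 5, 15)
  samples <- data.frame(
    sample_id = sprintf("S%03d", 1:(2 * n_part)),
    participant_id = rep(sprintf("P%03d", 1:n_part), 2),
    age = c(age1, age1 + gap),
    batch = "b1",
    lymphocytes = rnorm(2 * n_part, 2, 0.3),
    monocytes = rnorm(2 * n_part, 0.5, 0.1),
    neutrophils = rnorm(2 * n_part, 4, 0.5),
    eosinophils = rnorm(2 * n_part, 0.2, 0.05),
    stringsAsFactors = FALSE
  )
  meth <- rep(base, 2) + 0.05 * samples$age + rnorm(2 * n_part, 0, 0.1)
  scores <- matrix(meth, nrow = 1, dimnames = list("w", samples$sample_id))
  fit <- fit_longitudinal(scores, samples)
  r <- fit$results
  expect_lt(abs(r$slope - 0.05), 2 * r$se)
})

test_that("the mixed-model LRT detects strong effects and stays calibrated", {
  sim <- small_sim(seed = 29, n_samples = 400, frac_age_affected = 1,
                   slope_per_year = 0.1, noise_sd = 0.3)
  aff <- sim$truth$affected_windows[1]
  strong <- mixed_model_lrt(sim$scores[aff, ], sim$samples)
  expect_lt(strong$p_value, 1e-6)
  # no-effect window: p should not be tiny
  null_win <- setdiff(seq_len(nrow(sim$scores)),
                      sim$truth$affected_windows)[1]
  weak <- mixed_model_lrt(sim$scores[null_win, ], sim$samples)
  expect_gt(weak$p_value, 1e-4)
  expect_error(mixed_model_lrt(rnorm(12),
                               data.frame(family_id = rep("F1", 12),
                                          age = 1:12)),
               "families")
})

test_that("mixed-model LRT approaches the fixed partial F without clustering", {
  # paired-up families with zero shared variance: LRT ~ fixed partial F
  s <- make_samples(500, seed = 77)
  s$family_id <- rep(sprintf("F%03d", seq_len(250)), each = 2)
  s$zygosity <- rep(sample(c("MZ", "DZ"), 250, replace = TRUE), each = 2)
  set.seed(78)
  meth <- rnorm(500, 5, 1) + 0.005 * s$age
  mixed <- mixed_model_lrt(meth, s)
  fixed <- fit_age_model(meth, s, age_model_spec(4, "age_response"))
  ratio <- mixed$p_value / fixed$p_value
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("mixed-model LRT type-I error is controlled", {
  sim <- small_sim(seed = 41, n_samples = 250, frac_age_affected = 0,
                   chrom_len = 3e5)
  set.seed(42)
  null_windows <- sample(seq_len(nrow(sim$scores)), 80)
  ps <- vapply(null_windows, function(i) {
    mixed_model_lrt(sim$scores[i, ], sim$samples)$p_value
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.12)
})

test_that("Bonferroni thresholds divide alpha by the test count", {
  expect_equal(signif(bonferroni_threshold(0.05, 598), 3), 8.36e-5)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 103), 0.05 / 103)
  expect_error(bonferroni_threshold(0.05, 0), "positive")
  expect_error(bonferroni_threshold(1.5, 10), "alpha")
  ms <- c(1, 10, 103, 598, 12.8e6)
  thr <- vapply(ms, function(m) bonferroni_threshold(0.05, m), numeric(1))
  expect_true(all(diff(thr) < 0))  # strictly decreasing in m
})

test_that("tRNA summaries pick min-p windows and apply the any-overlap rule", {
  results <- data.frame(
    window = c("w1", "w2", "w3", "w4"),
    slope = c(0.01, 0.05, -0.02, 0.03),
    se = 0.01, p_value = c(0.2, 3e-6, 0.5, 3e-6),
    flag = NA_character_, stringsAsFactors = FALSE
  )
  map <- data.frame(window_index = c(1, 2, 3, 2, 4),
                    window = c("w1", "w2", "w3", "w2", "w4"),
                    feature = c("tA", "tA", "tB", "tC", "tC"),
                    stringsAsFactors = FALSE)
  thr <- list(study_wide = 8.36e-5, genome_wide = 4.34e-9)
  out <- summarize_by_trna(results, map, thr)
  a <- out[out$feature == "tA", ]
  expect_equal(a$best_window, "w2")
  expect_equal(a$p_value, 3e-6)
  expect_true(a$study_wide_significant)
  expect_false(a$genome_wide_significant)
  expect_equal(a$direction, "hyper")
  b <- out[out$feature == "tB", ]
  expect_false(b$study_wide_significant)
  expect_equal(b$direction, "hypo")
  # shared significant window w2 makes both tA and tC significant
  expect_true(out$study_wide_significant[out$feature == "tC"])
  # tie on p broken by larger |slope|: tC has w2 (0.05) and w4 (0.03)
  expect_equal(out$best_window[out$feature == "tC"], "w2")
  # uncovered gene flagged
  feats <- data.frame(name = c("tA", "tB", "tC", "tD"),
                      stringsAsFactors = FALSE)
  out2 <- summarize_by_trna(results, map, thr, features = feats)
  expect_true(out2$no_coverage[out2$feature == "tD"])
  expect_false(out2$study_wide_significant[out2$feature == "tD"])
  # missing window result is an error
  bad_map <- rbind(map, data.frame(window_index = 9, window = "w9",
                                   feature = "tE", stringsAsFactors = FALSE))
  expect_error(summarize_by_trna(results, bad_map, thr), "w9")
})
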