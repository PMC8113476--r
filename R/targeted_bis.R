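#' Read a Bismark-coverage-style count file
#'
#' Expects the six-column coverage format: chrom, start, end, methylation
#' percentage, methylated reads, unmethylated reads (1-based positions,
#' start = end for a CpG). Total reads are reconstructed from the two count
#' columns.
#'
#' @param path TSV path (no header).
#' @param pool_id,pool_age Pool identity and mean age attached to every row.
#' @return Data.frame: `chrom`, `pos`, `meth_reads`, `total_reads`,
#'   `pool_id`, `pool_age`.
#' @export
read_bismark_cov <- function(path, pool_id = NA_character_,
                             pool_age = NA_real_) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stop("expected >= 6 columns in coverage file: ", path)
  out <- data.frame(
    chrom = as.character(df[[1L]]), pos = as.integer(df[[2L]]),
    meth_reads = as.integer(df[[5L]]),
    total_reads = as.integer(df[[5L]]) + as.integer(df[[6L]]),
    pool_id = pool_id, pool_age = pool_age, stringsAsFactors = FALSE
  )
  if (any(out$meth_reads > out$total_reads)) stop("meth_reads > total_reads")
  out
}

#' Minimum-coverage filter for CpG counts
#'
#' Retains records with at least `min_reads` total reads. Idempotent;
#' raising `min_reads` never adds records.
#'
#' @param counts CpG count table with `total_reads`.
#' @param min_reads Minimum depth (default 25, the targeted-BiS threshold).
#' @return Filtered table.
#' @export
coverage_filter <- function(counts, min_reads = 25) {
  counts[counts$total_reads >= min_reads, , drop = FALSE]
}

#' RRBS-style QC: depth filter plus per-feature data-point requirement
#'
#' The RRBS preset requires more than `min_reads` reads per CpG record and
#' strictly more than `min_sites` retained data points per feature, dropping
#' whole features below that.
#'
#' @param counts CpG count table with `total_reads` and `feature`.
#' @param min_reads Strict depth threshold (default 50, i.e. keep > 50).
#' @param min_sites Strict per-feature retained data-point threshold
#'   (default 10, i.e. keep features with > 10).
#' @return Filtered table.
#' @export
rrbs_filter <- function(counts, min_reads = 50, min_sites = 10) {
  stopifnot("feature" %in% names(counts))
  kept <- counts[counts$total_reads > min_reads, , drop = FALSE]
  n_per <- table(kept$feature)
  keep_features <- names(n_per)[n_per > min_sites]
  kept[kept$feature %in% keep_features, , drop = FALSE]
}

#' Assign CpG records to features by position
#'
#' A 1-based CpG position `pos` falls in a BED feature `[start, end)` when
#' `start < pos <= end`.
#'
#' @param counts CpG count table with `chrom`, `pos`.
#' @param features Feature table (chrom/start/end/name).
#' @return `counts` with a `feature` column; unassigned records dropped.
#' @export
assign_cpgs_to_features <- function(counts, features) {
  feat <- rep(NA_character_, nrow(counts))
  for (j in seq_len(nrow(features))) {
    hit <- counts$chrom == features$chrom[j] &
      counts$pos > features$start[j] & counts$pos <= features$end[j]
    feat[hit] <- features$name[j]
  }
  counts$feature <- feat
  counts[!is.na(feat), , drop = FALSE]
}

#' Per-pool methylation proportions for one region
#'
#' Averages technical replicates within pool (rows sharing `pool_id` and
#' `pos`), then returns a CpG-by-pool matrix of methylation proportions.
#'
#' @param counts QC-passing CpG count table for one feature.
#' @return Matrix: rows CpG positions, columns pool ids, values proportions.
#' @export
region_pool_matrix <- function(counts) {
  prop <- counts$meth_reads / counts$total_reads
  agg <- stats::aggregate(prop,
                          by = list(pos = counts$pos, pool = counts$pool_id),
                          FUN = mean)
  pools <- sort(unique(agg$pool))
  pos <- sort(unique(agg$pos))
  m <- matrix(NA_real_, nrow = length(pos), ncol = length(pools),
              dimnames = list(as.character(pos), pools))
  m[cbind(match(agg$pos, pos), match(agg$pool, pools))] <- agg$x
  m
}

#' Pairwise differential methylation between two age groups for one region
#'
#' Pools are the replicates: per CpG, methylation is averaged over each
#' group's pools, and the paired t-test pairs CpG sites across the two
#' groups over the region, giving the region's primary p-value. The
#' methylation difference `delta` is the mean over CpGs of (group b -
#' group a). Per-CpG two-sample (unpaired) t-test p-values over the pools
#' are additionally combined with [combine_pvalues()]; both are reported.
#' Only CpGs with data in every compared pool enter.
#'
#' A single-CpG region cannot be CpG-paired and returns the per-CpG test
#' alone. When all per-CpG differences are identical the paired t statistic
#' degenerates: p is reported as 1 if the common difference is zero and as
#' the limiting 0 otherwise, with a `zero_variance` flag.
#'
#' @param region_counts QC-passing CpG counts for one feature (all pools).
#' @param group_a_pools,group_b_pools Pool ids of the two groups (b is the
#'   older group by convention, so positive delta = hypermethylation).
#' @return List of class `pairwise_diff`: `feature`, `num_cpgs`, `delta`,
#'   `p_paired`, `per_cpg_p`, `combined_p`, `flag`.
#' @export
pairwise_region_test <- function(region_counts, group_a_pools,
                                 group_b_pools) {
  feature <- unique(region_counts$feature)
  if (length(feature) != 1L) stop("region_counts must cover one feature")
  m <- region_pool_matrix(region_counts)
  pools_needed <- c(group_a_pools, group_b_pools)
  missing_pool <- setdiff(pools_needed, colnames(m))
  if (length(missing_pool) > 0L) {
    stop("no data for pool(s): ", paste(missing_pool, collapse = ", "))
  }
  complete <- stats::complete.cases(m[, pools_needed, drop = FALSE])
  m <- m[complete, , drop = FALSE]
  if (nrow(m) == 0L) stop("no shared CpGs passing QC in both groups")

  mean_a <- rowMeans(m[, group_a_pools, drop = FALSE])
  mean_b <- rowMeans(m[, group_b_pools, drop = FALSE])
  delta <- mean(mean_b - mean_a)

  per_cpg_p <- vapply(seq_len(nrow(m)), function(i) {
    tryCatch(
      stats::t.test(m[i, group_b_pools], m[i, group_a_pools])$p.value,
      error = function(e) NA_real_)
  }, numeric(1))

  flag <- NA_character_
  if (nrow(m) >= 2L) {
    d <- mean_b - mean_a
    # degenerate at floating-point resolution, not just exact zeros
    if (stats::sd(d) <= 1e-12 * max(abs(d), 1)) {
      flag <- "zero_variance"
      p_paired <- if (all(abs(d) <= 1e-15)) 1 else 0  # documented limit
    } else {
      p_paired <- stats::t.test(mean_b, mean_a, paired = TRUE)$p.value
    }
  } else {
    p_paired <- NA_real_
    flag <- "single_cpg"
  }
  usable <- per_cpg_p[!is.na(per_cpg_p)]
  combined_p <- if (length(usable) > 0) combine_pvalues(usable)$p_value else
    NA_real_
  structure(list(feature = feature, num_cpgs = nrow(m), delta = delta,
                 p_paired = p_paired, per_cpg_p = per_cpg_p,
                 combined_p = combined_p, flag = flag),
            class = "pairwise_diff")
}

#' Combine p-values by Fisher's method (with optional Brown adjustment)
#'
#' Fisher: `X = -2 * sum(log p)` referred to chi-squared with `2k` degrees
#' of freedom; a single p-value is returned unchanged. The Brown-type
#' variant rescales the chi-squared reference using the correlation
#' structure of the underlying data (Kost-McDermott polynomial
#' approximation for the covariance of `-2 log p` terms), for dependent
#' tests such as neighbouring CpGs in one region.
#'
#' @param ps Vector of p-values in (0, 1]; exact zeros are clipped to the
#'   smallest positive double with a warning.
#' @param method `"fisher"` (default) or `"brown"`.
#' @param data For `method = "brown"`: matrix with one row per p-value and
#'   one column per observation, used to estimate inter-test correlation.
#' @return List: `p_value`, `statistic`, `df`, `method`.
#' @export
combine_pvalues <- function(ps, method = c("fisher", "brown"), data = NULL) {
  method <- match.arg(method)
  if (length(ps) == 0L) stop("no p-values to combine")
  if (any(is.na(ps)) || any(ps < 0) || any(ps > 1)) {
    stop("p-values must be in (0, 1]")
  }
  if (any(ps == 0)) {
    warning("p = 0 clipped to smallest positive double")
    ps[ps == 0] <- .Machine$double.xmin
  }
  k <- length(ps)
  X <- -2 * sum(log(ps))
  if (method == "fisher" || k == 1L) {
    return(list(p_value = stats::pchisq(X, df = 2 * k, lower.tail = FALSE),
                statistic = X, df = 2 * k, method = "fisher"))
  }
  if (is.null(data) || nrow(data) != k) {
    stop("brown method needs a data matrix with one row per p-value")
  }
  rho <- stats::cor(t(data))
  covsum <- 0
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      r <- rho[i, j]
      covsum <- covsum + r * (3.263 + 0.710 * r + 0.027 * r^2)
    }
  }
  e_x <- 2 * k
  var_x <- 4 * k + 2 * covsum
  c_scale <- var_x / (2 * e_x)
  df <- 2 * e_x^2 / var_x
  list(p_value = stats::pchisq(X / c_scale, df = df, lower.tail = FALSE),
       statistic = X, df = df, method = "brown")
}

#' One-sided Wilcoxon rank-sum comparison with shift estimate
#'
#' Wilcoxon/Mann-Whitney rank-sum test with the first-sample W convention
#' (rank sum of the first sample minus its minimum), exact for small
#' tie-free samples and normal-approximated with tie correction otherwise,
#' plus the Hodges-Lehmann shift estimate and the matching one-sided
#' confidence interval. `alternative` refers to the first sample, as in
#' [stats::wilcox.test()].
#'
#' @param values_a,values_b Numeric samples.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @param conf_level Confidence level (default 0.95).
#' @return List: `W`, `p_value`, `estimate` (Hodges-Lehmann), `conf_int`,
#'   `method`.
#' @export
rank_sum_compare <- function(values_a, values_b,
                             alternative = c("two.sided", "greater", "less"),
                             conf_level = 0.95) {
  alternative <- match.arg(alternative)
  if (length(values_a) == 0L || length(values_b) == 0L) {
    stop("both groups must be non-empty")
  }
  pooled <- c(values_a, values_b)
  W_manual <- sum(rank(pooled)[seq_along(values_a)]) -
    length(values_a) * (length(values_a) + 1) / 2
  if (length(unique(pooled)) == 1L) {
    return(list(W = W_manual, p_value = 1, estimate = 0,
                conf_int = c(-Inf, Inf), method = "degenerate"))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, alternative = alternative,
                       conf.int = TRUE, conf.level = conf_level))
  list(W = unname(wt$statistic), p_value = wt$p.value,
       estimate = unname(wt$estimate), conf_int = as.numeric(wt$conf.int),
       method = wt$method)
}

#' Simple linear regression of pooled methylation on pool age
#'
#' Fits both orientations across pools: methylation on age (slope in
#' proportion per year, the interpretable rate) and age on methylation; the
#' F-test p-value is shared. Constant methylation yields slope 0 with a
#' flagged p of 1.
#'
#' @param meth Per-pool methylation proportions.
#' @param pool_ages Per-pool mean ages (years).
#' @return List: `slope_meth_per_year`, `slope_age_per_meth`, `p_value`,
#'   `r_squared`, `flag`.
#' @export
fit_pool_age_regression <- function(meth, pool_ages) {
  ok <- !is.na(meth) & !is.na(pool_ages)
  meth <- meth[ok]; pool_ages <- pool_ages[ok]
  if (length(meth) < 3L) stop("need >= 3 pools with data")
  if (stats::var(meth) == 0) {
    return(list(slope_meth_per_year = 0, slope_age_per_meth = NA_real_,
                p_value = 1, r_squared = 0, flag = "zero_variance"))
  }
  fit <- stats::lm(meth ~ pool_ages)
  s <- summary(fit)
  fs <- s$fstatistic
  p <- stats::pf(fs[1L], fs[2L], fs[3L], lower.tail = FALSE)
  rev_fit <- stats::lm(pool_ages ~ meth)
  list(slope_meth_per_year = unname(stats::coef(fit)[2L]),
       slope_age_per_meth = unname(stats::coef(rev_fit)[2L]),
       p_value = unname(p), r_squared = s$r.squared, flag = NA_character_)
}

#' Run all pairwise age-group comparisons for every region
#'
#' Produces the standard report shape: one row per (region, age-group
#' comparison) with the CpG count, region p-value and methylation delta.
#'
#' @param counts QC-passing CpG count table with `feature`, `pool_id`,
#'   `pool_age`.
#' @param design Pool design table mapping pools to age groups
#'   (`pool_id`, `age_group`).
#' @return Data.frame: `feature`, `num_cpgs`, `comparison`, `p_value`
#'   (paired-by-CpG), `combined_p`, `delta`, `flag`.
#' @export
pairwise_all_regions <- function(counts, design) {
  groups <- split(design$pool_id, design$age_group)
  ages <- sort(as.numeric(names(groups)))
  combos <- utils::combn(ages, 2, simplify = FALSE)
  feats <- unique(counts$feature)
  rows <- list()
  for (f in feats) {
    sub <- counts[counts$feature == f, , drop = FALSE]
    for (cmb in combos) {
      a <- as.character(cmb[1]); b <- as.character(cmb[2])
      res <- tryCatch(
        pairwise_region_test(sub, groups[[a]], groups[[b]]),
        error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, num_cpgs = res$num_cpgs,
        comparison = sprintf("%s vs. %s", a, b),
        p_value = res$p_paired, combined_p = res$combined_p,
        delta = res$delta, flag = res$flag, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(feature = character(), num_cpgs = integer(),
                      comparison = character(), p_value = numeric(),
                      combined_p = numeric(), delta = numeric(),
                      flag = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
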