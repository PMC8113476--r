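#' Build a 2x2 enrichment table from significance flags
#'
#' @param significant Logical vector over all windows.
#' @param in_feature Logical vector: window overlaps the feature set.
#' @return Named list `a` (significant in feature set), `b` (non-significant
#'   in feature set), `c` (significant outside), `d` (non-significant
#'   outside).
#' @export
enrichment_table <- function(significant, in_feature) {
  stopifnot(length(significant) == length(in_feature))
  list(a = sum(significant & in_feature),
       b = sum(!significant & in_feature),
       c = sum(significant & !in_feature),
       d = sum(!significant & !in_feature))
}

#' One-sided Fisher's exact enrichment test
#'
#' Tests whether the feature set holds more significant windows than expected
#' given the margins: the p-value is the hypergeometric tail probability
#' P(X >= a). The odds ratio is the sample odds ratio (a*d)/(b*c); when
#' `b*c = 0` it is `Inf` for a non-zero numerator and `NaN` for the 0/0 case.
#'
#' @param table List or vector with elements `a`, `b`, `c`, `d` as in
#'   [enrichment_table()].
#' @param alternative Passed to [stats::fisher.test()] (default `"greater"`).
#' @return List: `odds_ratio`, `p_value`.
#' @export
fisher_enrichment <- function(table, alternative = "greater") {
  a <- table[["a"]]; b <- table[["b"]]; c <- table[["c"]]; d <- table[["d"]]
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0)) stop("table cells must be >= 0")
  m <- matrix(c(a, b, c, d), nrow = 2,
              dimnames = list(c("sig", "nonsig"), c("feature", "background")))
  p <- stats::fisher.test(m, alternative = alternative)$p.value
  # sample OR; IEEE division gives Inf for x/0 (x > 0) and NaN for 0/0
  list(odds_ratio = (a * d) / (b * c), p_value = p)
}

#' Group windows into CpG-density sampling strata
#'
#' Windows below the density threshold form one stratum per exact CpG count
#' (for fixed-length windows, count and density are interchangeable); all
#' windows at or above the threshold (45 CpGs per 500 bp = 18% by default)
#' are pooled into a single stratum, because CpG-island-density windows are
#' consistently hypomethylated and too few to sample per exact count.
#'
#' @param windows Window table with `cpg_count` and coordinates, or a bare
#'   integer vector of CpG counts (assumed 500 bp windows).
#' @param pool_threshold_pct Density threshold in percent (default 18).
#' @param indices Optional indices these windows refer to (defaults to
#'   `seq_along`); useful when building pools over a background subset.
#' @return List of class `density_pools`: `strata` (named list of index
#'   vectors, one per exact CpG count plus `"pooled"`), `threshold_count`.
#' @export
build_density_pools <- function(windows, pool_threshold_pct = 18,
                                indices = NULL) {
  if (is.data.frame(windows)) {
    counts <- windows$cpg_count
    len <- windows$end - windows$start
  } else {
    counts <- as.integer(windows)
    len <- rep(500L, length(counts))
  }
  if (is.null(indices)) indices <- seq_along(counts)
  stopifnot(length(indices) == length(counts))
  # density_pct = 200 * count / len  =>  count threshold = pct * len / 200
  thr <- unique(ceiling(pool_threshold_pct * len / 200))
  if (length(thr) == 0L) thr <- ceiling(pool_threshold_pct * 500 / 200)
  if (length(thr) != 1L) stop("mixed window lengths are not supported")
  key <- ifelse(counts >= thr, "pooled", as.character(counts))
  strata <- split(indices, key)
  structure(list(strata = strata, threshold_count = thr),
            class = "density_pools")
}

# stratum keys for a set of feature-window CpG counts
.stratum_keys <- function(counts, threshold_count) {
  ifelse(counts >= threshold_count, "pooled", as.character(counts))
}

#' Draw one CpG-density-matched random window set
#'
#' Samples, without replacement within the draw, the same number of
#' background windows as the feature set holds in every density stratum, so
#' the sampled set reproduces the feature set's CpG-count histogram exactly
#' below the pooled threshold and its total count above it.
#'
#' @param feature_counts CpG counts of the feature windows.
#' @param pools A `density_pools` built over the background windows.
#' @return Integer vector of sampled background window indices, of length
#'   `length(feature_counts)`.
#' @export
sample_matched_set <- function(feature_counts, pools) {
  stopifnot(inherits(pools, "density_pools"))
  keys <- .stratum_keys(feature_counts, pools$threshold_count)
  need <- table(keys)
  out <- vector("list", length(need))
  for (i in seq_along(need)) {
    key <- names(need)[i]
    k <- as.integer(need[[i]])
    pool <- pools$strata[[key]]
    if (is.null(pool) || length(pool) < k) {
      stop("background stratum exhausted for CpG count ", key,
           " (need ", k, ", have ", length(pool), ")")
    }
    out[[i]] <- pool[sample.int(length(pool), k)]
  }
  unlist(out, use.names = FALSE)
}

#' CpG-density-matched permutation enrichment test
#'
#' Counts the significant windows in the feature set, then draws `n_perm`
#' random window sets matched to the feature set's CpG density distribution
#' (exact-count strata below the 18% threshold, one pooled stratum above)
#' from the background (feature windows are excluded from the sampling
#' pool), and counts significant windows in each. With `r` the number of
#' permutations whose count is at least the observed count, the empirical
#' p-value is `(r + 1) / (n_perm + 1)`, which can never reach zero.
#'
#' Direction-specific questions (e.g. hypermethylation only) are asked by
#' passing direction-restricted `significant` flags.
#'
#' @param feature_idx Indices (into `windows`) of feature-overlapping
#'   windows.
#' @param windows Window table with `cpg_count`.
#' @param significant Logical vector over all windows.
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed.
#' @param pool_threshold_pct Density pooling threshold (default 18).
#' @return List of class `permutation_result`: `observed`, `perm_counts`,
#'   `r`, `n_perm`, `empirical_p`.
#' @export
permutation_enrichment <- function(feature_idx, windows, significant,
                                   n_perm = 1000, seed = 1L,
                                   pool_threshold_pct = 18) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  counts <- if (is.data.frame(windows)) windows$cpg_count else
    as.integer(windows)
  stopifnot(length(significant) == length(counts))
  feature_idx <- sort(unique(feature_idx))
  observed <- sum(significant[feature_idx])
  bg_idx <- setdiff(seq_along(counts), feature_idx)
  pools <- build_density_pools(
    if (is.data.frame(windows)) windows[bg_idx, , drop = FALSE]
    else counts[bg_idx],
    pool_threshold_pct = pool_threshold_pct, indices = bg_idx)
  feature_counts <- counts[feature_idx]
  keys <- .stratum_keys(feature_counts, pools$threshold_count)
  need <- table(keys)
  # pre-resolve stratum pools once; flag shortfalls before permuting
  pool_list <- lapply(names(need), function(key) {
    pool <- pools$strata[[key]]
    if (is.null(pool) || length(pool) < need[[key]]) {
      stop("background stratum exhausted for CpG count ", key,
           " (need ", need[[key]], ", have ", length(pool), ")")
    }
    pool
  })
  k_need <- as.integer(need)
  sig <- as.logical(significant)
  set.seed(seed)
  perm_counts <- integer(n_perm)
  for (p in seq_len(n_perm)) {
    tot <- 0L
    for (s in seq_along(pool_list)) {
      pool <- pool_list[[s]]
      tot <- tot + sum(sig[pool[sample.int(length(pool), k_need[s])]])
    }
    perm_counts[p] <- tot
  }
  r <- sum(perm_counts >= observed)
  structure(list(observed = observed, perm_counts = perm_counts, r = r,
                 n_perm = n_perm, empirical_p = (r + 1) / (n_perm + 1)),
            class = "permutation_result")
}

#' @exportS3Method base::print
print.permutation_result <- function(x, ...) {
  cat("CpG-density-matched permutation enrichment\n")
  cat("  observed significant windows:", x$observed, "\n")
  cat("  permutations:", x$n_perm,
      " with count >= observed:", x$r, "\n")
  cat("  empirical p-value:", format(x$empirical_p, digits = 6), "\n")
  invisible(x)
}
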