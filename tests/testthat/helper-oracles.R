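# Independent brute-force oracles used across test files. These deliberately
# avoid the package's own algorithms: clustering via transitive closure on a
# pairwise gap relation, Fisher via hypergeometric enumeration, rank-sum via
# exhaustive relabelling, OLS via the normal equations.

# single-linkage components by boolean transitive closure, then both filters
oracle_cluster <- function(genes, max_gap = 5e6, min_genes = 5,
                           min_density = 5) {
  n <- nrow(genes)
  if (n == 0) return(data.frame())
  gap <- function(i, j) {
    if (genes$chrom[i] != genes$chrom[j]) return(Inf)
    lo <- max(genes$start[i], genes$start[j])
    hi <- min(genes$end[i], genes$end[j])
    max(0, lo - hi)
  }
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- gap(i, j) <= max_gap
  }
  # transitive closure
  repeat {
    nxt <- adj | ((adj %*% adj) > 0)
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cid <- cid + 1L
      comp[adj[i, ]] <- cid
    }
  }
  rows <- lapply(split(seq_len(n), comp), function(idx) {
    span_start <- min(genes$start[idx])
    span_end <- max(genes$end[idx])
    k <- length(idx)
    dens <- k / ((span_end - span_start) / 1e6)
    if (k < min_genes || dens < min_density) return(NULL)
    data.frame(chrom = genes$chrom[idx[1]], span_start = span_start,
               span_end = span_end, n_genes = k,
               members = paste(sort(genes$name[idx]), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out <- out[order(out$chrom, out$span_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_gene_set <- function(n, n_chroms = 2, span = 2e7) {
  chrom <- sample(sprintf("chr%d", seq_len(n_chroms)), n, replace = TRUE)
  start <- sample.int(span, n)
  data.frame(chrom = chrom, start = start, end = start + sample(60:90, n,
                                                                replace = TRUE),
             name = sprintf("g%03d", seq_len(n)), stringsAsFactors = FALSE)
}

# one-sided (greater) Fisher p by direct hypergeometric enumeration
oracle_fisher_greater <- function(a, b, c, d) {
  K <- a + c          # significant windows in the population
  n_pop <- a + b + c + d
  n_draw <- a + b     # feature-set size
  xs <- max(0, n_draw - (n_pop - K)):min(K, n_draw)
  probs <- exp(lchoose(K, xs) + lchoose(n_pop - K, n_draw - xs) -
                 lchoose(n_pop, n_draw))
  sum(probs[xs >= a])
}

# exact rank-sum p by exhaustive relabelling of the pooled sample (no ties)
oracle_ranksum <- function(a, b, alternative) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  W_of <- function(idx) sum(rank(pooled)[idx]) - na * (na + 1) / 2
  W_obs <- W_of(seq_len(na))
  all_sets <- utils::combn(n, na)
  W_all <- apply(all_sets, 2, W_of)
  switch(alternative,
         greater = mean(W_all >= W_obs),
         less = mean(W_all <= W_obs),
         two.sided = min(1, 2 * min(mean(W_all >= W_obs),
                                    mean(W_all <= W_obs))))
}

# OLS slope, se and partial-F p for the last column of X via normal equations
oracle_ols <- function(y, X) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  n <- length(y)
  p <- ncol(X)
  sigma2 <- sum(res^2) / (n - p)
  se <- sqrt(diag(solve(XtX)) * sigma2)
  X0 <- X[, -p, drop = FALSE]
  beta0 <- solve(crossprod(X0), crossprod(X0, y))
  rss0 <- sum((y - X0 %*% beta0)^2)
  fstat <- (rss0 - sum(res^2)) / sigma2
  list(slope = unname(beta[p]), se = unname(se[p]),
       p = stats::pf(fstat, 1, n - p, lower.tail = FALSE))
}

# small, fast simulated study used by several files
small_sim <- function(seed = 42, n_samples = 150, n_trna = 20,
                      chrom_len = 4e5, ...) {
  simulate_study(simulation_config(
    seed = seed, n_samples = n_samples, n_trna = n_trna, n_chroms = 1,
    chrom_len = chrom_len, ...))
}
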