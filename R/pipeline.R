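#' Write a per-stage run manifest
#'
#' Records the stage name, package version, parameters, seed, wall time and
#' md5 checksums of the stage outputs, in JSON, so a deterministic stage can
#' be re-run and verified bit-identically.
#'
#' @param out_dir Output directory.
#' @param stage Stage name.
#' @param params Named list of stage parameters (seed included).
#' @param files Character vector of output file paths.
#' @param elapsed Elapsed seconds.
#' @return Invisible manifest path.
#' @export
write_manifest <- function(out_dir, stage, params, files, elapsed = NA_real_) {
  manifest <- list(
    stage = stage,
    package = "trnameth",
    version = as.character(utils::packageVersion("trnameth")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = params,
    elapsed_seconds = elapsed,
    outputs = lapply(files, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
  )
  path <- file.path(out_dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

.log_stage <- function(stage, seed, msg) {
  message(sprintf("[%s] %s seed=%s %s",
                  format(Sys.time(), "%H:%M:%S"), stage,
                  if (is.null(seed)) "-" else seed, msg))
}

#' Simulate a study and write its inputs to disk
#'
#' @param config A [simulation_config()]; its seed drives all randomness.
#' @param out_dir Directory for the generated annotation BED, window table,
#'   score matrix, sample metadata, truth record and config echo.
#' @return Invisible named vector of written paths.
#' @export
run_simulate <- function(config = simulation_config(), out_dir) {
  if (is.null(config$seed) || is.na(config$seed)) {
    stop("a seed is required for simulation")
  }
  t0 <- proc.time()[["elapsed"]]
  sim <- simulate_study(config)
  paths <- write_simulated_study(sim, out_dir)
  .log_stage("simulate", config$seed,
             sprintf("%d windows x %d samples, %d tRNAs",
                     nrow(sim$windows), nrow(sim$samples), nrow(sim$genes)))
  write_manifest(out_dir, "simulate", unclass(config), unname(paths),
                 proc.time()[["elapsed"]] - t0)
  invisible(paths)
}

.read_study_dir <- function(dir) {
  need <- c(genes = "trna_genes.bed", windows = "windows.tsv",
            scores = "score_matrix.tsv", samples = "samples.tsv")
  paths <- file.path(dir, need)
  absent <- need[!file.exists(paths)]
  if (length(absent) > 0L) {
    stop("study directory missing input(s): ", paste(absent, collapse = ", "))
  }
  windows <- utils::read.delim(file.path(dir, "windows.tsv"),
                               stringsAsFactors = FALSE)
  if (!all(c("chrom", "start", "end", "name", "cpg_count") %in%
           names(windows))) {
    stop("windows.tsv schema mismatch: needs chrom/start/end/name/cpg_count")
  }
  samples <- utils::read.delim(file.path(dir, "samples.tsv"),
                               stringsAsFactors = FALSE)
  list(genes = read_feature_bed(file.path(dir, "trna_genes.bed")),
       windows = windows,
       scores = read_score_matrix(file.path(dir, "score_matrix.tsv")),
       samples = samples)
}

#' Fit age models over a study directory and summarise per tRNA
#'
#' Quantile-normalises the score matrix, fits the requested model at every
#' window, computes study-wide (per tRNA count) and genome-wide (per window
#' count) Bonferroni thresholds, and writes window results, tRNA summaries
#' and a threshold manifest.
#'
#' @param dir Study input directory (as written by [run_simulate()]).
#' @param out_dir Output directory.
#' @param model_id Age model (default 4: batch + blood cell counts).
#' @param direction Model direction (default `"meth_response"`).
#' @param alpha Family-wise error rate for both thresholds (default 0.05).
#' @param normalize Quantile-normalise scores first (default TRUE).
#' @return Invisible list: `results`, `summary`, `thresholds`.
#' @export
run_age_models <- function(dir, out_dir, model_id = 4,
                           direction = "meth_response", alpha = 0.05,
                           normalize = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  study <- .read_study_dir(dir)
  spec <- age_model_spec(model_id, direction)
  missing_cov <- setdiff(setdiff(spec$covariates, "participant_id"),
                         names(study$samples))
  if (length(missing_cov) > 0L) {
    stop("samples.tsv lacks covariate column(s): ",
         paste(missing_cov, collapse = ", "))
  }
  scores <- if (normalize) quantile_normalize(study$scores) else study$scores
  results <- fit_all_windows(scores, study$samples, spec)
  map <- map_windows_to_features(study$windows, study$genes)
  thresholds <- list(
    alpha = alpha,
    m_study = nrow(study$genes), m_genome = nrow(study$windows),
    study_wide = bonferroni_threshold(alpha, nrow(study$genes)),
    genome_wide = bonferroni_threshold(alpha, nrow(study$windows))
  )
  summary <- summarize_by_trna(results, map, thresholds,
                               features = study$genes)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res_path <- file.path(out_dir, "window_results.tsv")
  sum_path <- file.path(out_dir, "trna_summary.tsv")
  results_out <- cbind(results, model_id = spec$model_id)
  utils::write.table(results_out, res_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(summary, sum_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  .log_stage("age_models", NULL,
             sprintf("model %s: %d/%d tRNAs study-wide significant",
                     spec$model_id, sum(summary$study_wide_significant),
                     nrow(summary)))
  write_manifest(out_dir, "age_models",
                 c(list(dir = dir, model_id = model_id,
                        direction = direction, normalize = normalize),
                   thresholds),
                 c(res_path, sum_path), proc.time()[["elapsed"]] - t0)
  invisible(list(results = results, summary = summary,
                 thresholds = thresholds))
}

#' Permutation + Fisher enrichment over a study directory
#'
#' Flags windows significant at the genome-wide Bonferroni threshold from a
#' prior [run_age_models()] output (optionally hypermethylating only), then
#' runs the one-sided Fisher's exact test and the CpG-density-matched
#' permutation test for the tRNA window set.
#'
#' @param dir Study input directory.
#' @param results_dir Directory holding `window_results.tsv`.
#' @param out_dir Output directory.
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed for the permutation draws.
#' @param threshold Significance cutoff for flags; default genome-wide
#'   Bonferroni `alpha / n_windows`.
#' @param alpha Family-wise rate used when `threshold` is NULL.
#' @param direction `"hyper"` restricts flags to positive slopes (default),
#'   `"both"` uses all significant windows.
#' @param pool_threshold_pct Density pooling threshold (default 18).
#' @return Invisible list: `fisher`, `permutation`, `report_path`.
#' @export
run_enrich <- function(dir, results_dir, out_dir, n_perm = 1000, seed = 1L,
                       threshold = NULL, alpha = 0.05, direction = "hyper",
                       pool_threshold_pct = 18) {
  t0 <- proc.time()[["elapsed"]]
  study <- .read_study_dir(dir)
  res_path <- file.path(results_dir, "window_results.tsv")
  if (!file.exists(res_path)) stop("window_results.tsv not found in ",
                                   results_dir)
  results <- utils::read.delim(res_path, stringsAsFactors = FALSE)
  if (!identical(results$window, study$windows$name)) {
    stop("window results do not align with the study's window table")
  }
  if (is.null(threshold)) {
    threshold <- bonferroni_threshold(alpha, nrow(study$windows))
  }
  sig <- results$p_value < threshold
  if (direction == "hyper") sig <- sig & results$slope > 0
  map <- map_windows_to_features(study$windows, study$genes)
  feature_idx <- sort(unique(map$window_index))
  in_feature <- seq_len(nrow(study$windows)) %in% feature_idx
  fisher <- fisher_enrichment(enrichment_table(sig, in_feature))
  perm <- permutation_enrichment(feature_idx, study$windows, sig,
                                 n_perm = n_perm, seed = seed,
                                 pool_threshold_pct = pool_threshold_pct)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(
    n_windows = nrow(study$windows), n_feature_windows = length(feature_idx),
    significance_threshold = threshold, direction = direction,
    fisher_odds_ratio = fisher$odds_ratio, fisher_p = fisher$p_value,
    observed = perm$observed, r = perm$r, n_perm = perm$n_perm,
    empirical_p = perm$empirical_p
  )
  report_path <- file.path(out_dir, "enrichment_report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA)
  .log_stage("enrich", seed,
             sprintf("observed=%d r=%d empirical_p=%.3g fisher_p=%.3g",
                     perm$observed, perm$r, perm$empirical_p, fisher$p_value))
  write_manifest(out_dir, "enrich",
                 list(dir = dir, n_perm = n_perm, seed = seed,
                      threshold = threshold, direction = direction,
                      pool_threshold_pct = pool_threshold_pct),
                 report_path, proc.time()[["elapsed"]] - t0)
  invisible(list(fisher = fisher, permutation = perm,
                 report_path = report_path))
}

#' Cluster the tRNA annotation of a study directory
#'
#' @param dir Study input directory (uses `trna_genes.bed`).
#' @param out_dir Output directory.
#' @param max_gap,min_genes,min_density Passed to [cluster_trnas()].
#' @return Invisible cluster table.
#' @export
run_cluster <- function(dir, out_dir, max_gap = 5e6, min_genes = 5,
                        min_density = 5) {
  t0 <- proc.time()[["elapsed"]]
  genes <- read_feature_bed(file.path(dir, "trna_genes.bed"))
  clusters <- cluster_trnas(genes, max_gap, min_genes, min_density)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(out_dir, "trna_clusters.tsv")
  bed <- file.path(out_dir, "trna_clusters.bed")
  utils::write.table(clusters, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_cluster_bed(clusters, bed)
  .log_stage("cluster", NULL,
             sprintf("%d clusters holding %d genes", nrow(clusters),
                     sum(clusters$n_genes)))
  write_manifest(out_dir, "cluster",
                 list(dir = dir, max_gap = max_gap, min_genes = min_genes,
                      min_density = min_density),
                 c(tsv, bed), proc.time()[["elapsed"]] - t0)
  invisible(clusters)
}

#' Pooled bisulfite differential methylation over simulated (or real) counts
#'
#' Applies the minimum-coverage filter and runs every pairwise age-group
#' comparison per region plus the per-region pooled age regression, writing
#' a pairwise table (one row per region and comparison) and a regression
#' table.
#'
#' @param counts CpG count table with `feature`, `pool_id`, `pool_age`.
#' @param design Pool design table (`pool_id`, `age_group`).
#' @param out_dir Output directory.
#' @param min_reads Coverage threshold (default 25).
#' @return Invisible list: `pairwise`, `regression`.
#' @export
run_bis_diff <- function(counts, design, out_dir, min_reads = 25) {
  t0 <- proc.time()[["elapsed"]]
  kept <- coverage_filter(counts, min_reads)
  pw <- pairwise_all_regions(kept, design)
  reg_rows <- lapply(unique(kept$feature), function(f) {
    sub <- kept[kept$feature == f, , drop = FALSE]
    m <- region_pool_matrix(sub)
    pool_mean <- colMeans(m, na.rm = TRUE)
    ages <- design$mean_age[match(names(pool_mean), design$pool_id)]
    r <- tryCatch(fit_pool_age_regression(pool_mean, ages),
                  error = function(e) NULL)
    if (is.null(r)) return(NULL)
    data.frame(feature = f, slope_meth_per_year = r$slope_meth_per_year,
               p_value = r$p_value, r_squared = r$r_squared,
               stringsAsFactors = FALSE)
  })
  reg <- do.call(rbind, reg_rows)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pw_path <- file.path(out_dir, "pairwise_diff.tsv")
  reg_path <- file.path(out_dir, "pool_age_regression.tsv")
  utils::write.table(pw, pw_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(reg, reg_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  .log_stage("bis_diff", NULL,
             sprintf("%d regions, %d pairwise rows",
                     length(unique(kept$feature)), nrow(pw)))
  write_manifest(out_dir, "bis_diff", list(min_reads = min_reads),
                 c(pw_path, reg_path), proc.time()[["elapsed"]] - t0)
  invisible(list(pairwise = pw, regression = reg))
}
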