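#' Configuration for a synthetic windowed-methylome study
#'
#' Bundles every knob of the synthetic cohort and genome. The defaults emulate
#' the statistical structure of a large adult twin-cohort blood methylome
#' study: 3001 samples with full blood-count covariates, ages 16-82, a mostly
#' female cohort with monozygotic and dizygotic twin pairs, a minority of
#' participants revisited 5-16 years later, additive batch and cell-type
#' composition effects, and a genome scaled to desk size (two 1 Mb
#' chromosomes) carrying 100 planted tRNA genes whose windows skew CpG-denser
#' than background.
#'
#' @param seed RNG seed (integer).
#' @param n_chroms,chrom_len Number and length (bp) of simulated chromosomes.
#' @param window_size,window_step Window geometry in bp.
#' @param n_trna Number of planted tRNA genes.
#' @param frac_age_affected Fraction of tRNA genes given a true age effect.
#' @param slope_per_year True methylation change per year (score units/yr) at
#'   windows overlapping affected tRNAs.
#' @param noise_sd SD of Gaussian noise on the score scale.
#' @param batch_effect_sd SD of per-batch additive offsets; `n_batches`
#'   batches are used.
#' @param n_batches Number of processing batches.
#' @param celltype_effect Named vector of score change per unit cell count for
#'   lymphocytes, monocytes, neutrophils, eosinophils (applies to every
#'   window, mimicking composition effects).
#' @param celltype_age_slope Named vector of cell-count change per year of
#'   age; non-zero values make composition a confounder of age.
#' @param age_range Two-element vector of min/max ages in years.
#' @param n_samples Number of methylomes (samples, not participants).
#' @param twin_fraction Fraction of participants who are one of a twin pair.
#' @param mz_fraction Fraction of twin pairs that are monozygotic.
#' @param family_sd SD of the per-family random intercept shared by twins.
#' @param indiv_sd SD of the per-participant random intercept.
#' @param longitudinal_fraction Fraction of samples contributed by second
#'   visits of revisited participants.
#' @param revisit_gap_range Min/max years between visits for revisited
#'   participants.
#' @param trna_cpg_mu,trna_cpg_size Negative-binomial mean/size for CpG counts
#'   of tRNA-overlapping windows.
#' @param bg_cpg_mu,bg_cpg_size Negative-binomial mean/size for the sparse
#'   component of background window CpG counts.
#' @param bg_dense_frac Fraction of background windows drawn from a
#'   CpG-island-like dense component.
#' @param bg_dense_mu,bg_dense_size Negative-binomial mean/size of the dense
#'   background component.
#' @param baseline_max,baseline_halfsat Parameters of the monotone saturating
#'   density-to-baseline curve (score units; half-saturation in density %).
#' @param hypometh_level Baseline score for CpG-island-like windows at or
#'   above `hypometh_threshold_pct` density, which are consistently
#'   hypomethylated.
#' @param hypometh_threshold_pct Density (%) above which windows take the
#'   hypomethylated baseline (default 18).
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chroms = 2L, chrom_len = 1e6,
                              window_size = 500L, window_step = 250L,
                              n_trna = 100L,
                              frac_age_affected = 0.1,
                              slope_per_year = 0.02,
                              noise_sd = 0.5,
                              batch_effect_sd = 0.2,
                              n_batches = 4L,
                              celltype_effect = c(lymphocytes = 0.05,
                                                  monocytes = 0.02,
                                                  neutrophils = 0.03,
                                                  eosinophils = 0.01),
                              celltype_age_slope = c(lymphocytes = -0.005,
                                                     monocytes = 0,
                                                     neutrophils = 0.01,
                                                     eosinophils = 0),
                              age_range = c(16, 82),
                              n_samples = 3001L,
                              twin_fraction = 0.6,
                              mz_fraction = 0.7,
                              family_sd = 0.3,
                              indiv_sd = 0.2,
                              longitudinal_fraction = 0.18,
                              revisit_gap_range = c(5, 16),
                              trna_cpg_mu = 28, trna_cpg_size = 8,
                              bg_cpg_mu = 6, bg_cpg_size = 2,
                              bg_dense_frac = 0.12,
                              bg_dense_mu = 30, bg_dense_size = 4,
                              baseline_max = 8, baseline_halfsat = 5,
                              hypometh_level = 1,
                              hypometh_threshold_pct = 18) {
  cfg <- as.list(environment())
  stopifnot(cfg$noise_sd >= 0, cfg$batch_effect_sd >= 0,
            cfg$family_sd >= 0, cfg$indiv_sd >= 0,
            cfg$frac_age_affected >= 0, cfg$frac_age_affected <= 1,
            cfg$twin_fraction >= 0, cfg$twin_fraction <= 1,
            cfg$longitudinal_fraction >= 0, cfg$longitudinal_fraction <= 1,
            cfg$age_range[1] >= 0, cfg$age_range[2] <= 120,
            cfg$age_range[1] < cfg$age_range[2],
            cfg$n_samples >= 2, cfg$n_trna >= 1)
  class(cfg) <- "sim_config"
  cfg
}

# monotone saturating baseline in density, hypomethylated above the CGI-like
# threshold (dense windows behave like unmethylated CpG islands)
.baseline_from_density <- function(density_pct, cfg) {
  base <- cfg$baseline_max * density_pct / (density_pct + cfg$baseline_halfsat)
  base[density_pct >= cfg$hypometh_threshold_pct] <- cfg$hypometh_level
  base
}

.isotype_pool <- data.frame(
  isotype = c("iMet", "Ser", "Ile", "Leu", "Gly", "Glu", "Asp", "Val",
              "Thr", "Ala", "Arg", "Lys", "Pro", "His", "Gln", "Tyr"),
  anticodon = c("CAT", "AGA", "AAT", "AAG", "GCC", "TTC", "GTC", "AAC",
                "AGT", "AGC", "TCT", "CTT", "AGG", "GTG", "CTG", "GTA"),
  stringsAsFactors = FALSE
)

#' Simulate a complete windowed methylome study
#'
#' Generates, reproducibly from the config seed: a toy genome of sliding
#' windows with CpG counts (tRNA-overlapping windows skew CpG-denser than
#' background), a set of named tRNA genes a fraction of which carry a planted
#' linear age effect, a cohort sample table with twin/longitudinal structure,
#' batch labels and blood cell counts, and the windows-by-samples score
#' matrix:
#'
#' `score = baseline(density) + slope_per_year * age * affected(window)
#'  + batch + sum(celltype_effect * count) + participant/family intercepts
#'  + Gaussian noise`, floored at 0.
#'
#' @param config A [simulation_config()].
#' @return List of class `trna_sim` with elements `genes`, `windows` (with
#'   `cpg_count`, `cpg_density_pct`), `scores` (windows x samples matrix),
#'   `samples` (one row per methylome), `truth` (affected tRNA genes, their
#'   true slope, and affected window indices) and `config`.
#' @export
simulate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  chrom_sizes <- data.frame(
    chrom = sprintf("chr%d", seq_len(cfg$n_chroms)),
    length = rep(cfg$chrom_len, cfg$n_chroms), stringsAsFactors = FALSE
  )
  windows <- make_sliding_windows(chrom_sizes, cfg$window_size, cfg$window_step)
  if (cfg$n_trna * 3 > nrow(windows)) {
    stop("infeasible config: planted tRNA windows exceed the simulated genome")
  }

  ## ---- tRNA genes: non-overlapping random placements, gtRNAdb-style names
  slots_per_chrom <- floor((cfg$chrom_len - 200) / 1500)
  slot_grid <- expand.grid(chrom = chrom_sizes$chrom,
                           slot = seq_len(slots_per_chrom),
                           stringsAsFactors = FALSE)
  pick <- slot_grid[sample.int(nrow(slot_grid), cfg$n_trna), , drop = FALSE]
  lens <- sample(60:86, cfg$n_trna, replace = TRUE)
  iso <- .isotype_pool[sample.int(nrow(.isotype_pool), cfg$n_trna,
                                  replace = TRUE), , drop = FALSE]
  fam <- as.integer(ave(seq_len(cfg$n_trna), iso$isotype, FUN = seq_along))
  genes <- data.frame(
    chrom = pick$chrom,
    start = (pick$slot - 1L) * 1500 + sample(0:500, cfg$n_trna, replace = TRUE),
    stringsAsFactors = FALSE
  )
  genes$end <- genes$start + lens
  genes$name <- sprintf("tRNA-%s-%s-%d-1", iso$isotype, iso$anticodon, fam)
  genes$score <- "0"
  genes$strand <- sample(c("+", "-"), cfg$n_trna, replace = TRUE)
  parsed <- parse_trna_name(genes$name)
  genes <- cbind(genes, parsed)
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL

  ## ---- CpG counts: tRNA windows denser than background
  wf_map <- map_windows_to_features(windows, genes)
  is_trna_window <- seq_len(nrow(windows)) %in% wf_map$window_index
  max_cpg <- floor(cfg$window_size / 2)
  cpg <- integer(nrow(windows))
  # background is itself a mixture: mostly CpG-sparse, plus a CpG-island-like
  # dense tail so density matching has background members at tRNA-like counts
  n_bg <- sum(!is_trna_window)
  dense <- stats::runif(n_bg) < cfg$bg_dense_frac
  bg_counts <- integer(n_bg)
  bg_counts[!dense] <- stats::rnbinom(sum(!dense), mu = cfg$bg_cpg_mu,
                                      size = cfg$bg_cpg_size)
  bg_counts[dense] <- stats::rnbinom(sum(dense), mu = cfg$bg_dense_mu,
                                     size = cfg$bg_dense_size)
  cpg[!is_trna_window] <- bg_counts
  cpg[is_trna_window] <- stats::rnbinom(sum(is_trna_window),
                                        mu = cfg$trna_cpg_mu,
                                        size = cfg$trna_cpg_size)
  cpg <- pmin(cpg, max_cpg)
  windows$cpg_count <- cpg
  windows$cpg_density_pct <- cpg_density_pct(cpg, windows$end - windows$start)

  ## ---- cohort
  samples <- .simulate_cohort(cfg)

  ## ---- planted truth
  n_affected <- round(cfg$frac_age_affected * nrow(genes))
  affected_genes <- if (n_affected > 0) {
    sort(sample(genes$name, n_affected))
  } else character()
  affected_windows <- sort(unique(
    wf_map$window_index[wf_map$feature %in% affected_genes]))

  ## ---- score matrix
  baseline <- .baseline_from_density(windows$cpg_density_pct, cfg)
  batch_offset <- stats::rnorm(cfg$n_batches, 0, cfg$batch_effect_sd)
  names(batch_offset) <- sprintf("batch%d", seq_len(cfg$n_batches))
  ct <- as.matrix(samples[, names(cfg$celltype_effect), drop = FALSE])
  sample_shift <- batch_offset[samples$batch] +
    as.numeric(ct %*% cfg$celltype_effect) + samples$.participant_intercept
  age_term <- numeric(nrow(windows))
  age_term[affected_windows] <- cfg$slope_per_year
  scores <- outer(baseline, rep(1, nrow(samples))) +
    outer(age_term, samples$age) +
    matrix(sample_shift, nrow = nrow(windows), ncol = nrow(samples),
           byrow = TRUE) +
    matrix(stats::rnorm(nrow(windows) * nrow(samples), 0, cfg$noise_sd),
           nrow = nrow(windows))
  scores <- pmax(scores, 0)
  rownames(scores) <- windows$name
  colnames(scores) <- samples$sample_id
  samples$.participant_intercept <- NULL

  structure(list(
    genes = genes, windows = windows, scores = scores, samples = samples,
    truth = list(affected_genes = affected_genes,
                 affected_windows = affected_windows,
                 slope_per_year = cfg$slope_per_year),
    config = cfg
  ), class = "trna_sim")
}

# cohort with twin pairs, revisits, batch labels and age-trending cell counts
.simulate_cohort <- function(cfg) {
  n_revisit <- floor(cfg$longitudinal_fraction * cfg$n_samples / 2)
  n_participants <- cfg$n_samples - n_revisit
  n_twin_pairs <- floor(cfg$twin_fraction * n_participants / 2)

  participant_id <- sprintf("P%04d", seq_len(n_participants))
  family_id <- character(n_participants)
  zygosity <- rep(NA_character_, n_participants)
  fam <- 0L
  i <- 1L
  pair <- 0L
  while (pair < n_twin_pairs) {
    fam <- fam + 1L
    zy <- if (stats::runif(1) < cfg$mz_fraction) "MZ" else "DZ"
    family_id[i] <- family_id[i + 1L] <- sprintf("F%04d", fam)
    zygosity[i] <- zygosity[i + 1L] <- zy
    i <- i + 2L
    pair <- pair + 1L
  }
  if (i <= n_participants) {
    for (j in seq(i, n_participants)) {
      fam <- fam + 1L
      family_id[j] <- sprintf("F%04d", fam)
    }
  }

  age <- stats::runif(n_participants, cfg$age_range[1], cfg$age_range[2])
  # twins share an age
  if (n_twin_pairs > 0) {
    twin_first <- seq(1L, by = 2L, length.out = n_twin_pairs)
    age[twin_first + 1L] <- age[twin_first]
  }
  sex <- sample(c("F", "M"), n_participants, replace = TRUE,
                prob = c(0.93, 0.07))
  if (n_twin_pairs > 0) sex[twin_first + 1L] <- sex[twin_first]

  fam_eff <- stats::rnorm(fam, 0, cfg$family_sd)
  names(fam_eff) <- sprintf("F%04d", seq_len(fam))
  part_eff <- fam_eff[family_id] + stats::rnorm(n_participants, 0, cfg$indiv_sd)

  visits <- data.frame(
    participant_id = participant_id, family_id = family_id,
    zygosity = zygosity, age = age, sex = sex, visit = 1L,
    .participant_intercept = part_eff, stringsAsFactors = FALSE
  )
  if (n_revisit > 0) {
    idx <- sample.int(n_participants, n_revisit)
    gap <- stats::runif(n_revisit, cfg$revisit_gap_range[1],
                        cfg$revisit_gap_range[2])
    second <- visits[idx, , drop = FALSE]
    # keep second-visit ages inside the configured range
    second$age <- pmin(second$age + gap, cfg$age_range[2])
    second$visit <- 2L
    visits <- rbind(visits, second)
  }
  visits <- visits[order(visits$participant_id, visits$visit), , drop = FALSE]
  rownames(visits) <- NULL
  visits$sample_id <- sprintf("S%04d", seq_len(nrow(visits)))
  visits$batch <- sprintf("batch%d",
                          sample.int(cfg$n_batches, nrow(visits),
                                     replace = TRUE))

  ct_base <- c(lymphocytes = 2.0, monocytes = 0.5, neutrophils = 4.0,
               eosinophils = 0.2)
  ct_sd <- c(lymphocytes = 0.5, monocytes = 0.15, neutrophils = 1.0,
             eosinophils = 0.1)
  for (nm in names(ct_base)) {
    mu <- ct_base[[nm]] + cfg$celltype_age_slope[[nm]] * (visits$age - 50)
    visits[[nm]] <- pmax(stats::rnorm(nrow(visits), mu, ct_sd[[nm]]), 0)
  }
  cols <- c("sample_id", "participant_id", "family_id", "zygosity", "age",
            "sex", "batch", "visit", "lymphocytes", "monocytes",
            "neutrophils", "eosinophils", ".participant_intercept")
  visits[, cols]
}

#' Default pooled targeted-bisulfite study design
#'
#' Eight pools of age-matched individuals at four time points (about 4, 28,
#' 63 and 78 years; 190 contributors in total), two pools per time point; the
#' two youngest pools have 20 contributors each and the remainder 25, with
#' one all-male pool at age 4 and all-female pools otherwise.
#'
#' @return Data.frame with `pool_id`, `mean_age`, `age_group`, `sex`,
#'   `n_contributors`.
#' @export
pool_design_default <- function() {
  data.frame(
    pool_id = sprintf("Pool%d", 1:8),
    mean_age = c(4.07, 4.09, 28.07, 28.23, 63.40, 63.26, 77.96, 77.22),
    age_group = c(4, 4, 28, 28, 63, 63, 78, 78),
    sex = c("Male", rep("Female", 7)),
    n_contributors = c(20, 20, 25, 25, 25, 25, 25, 25),
    stringsAsFactors = FALSE
  )
}

#' Simulate pooled targeted-bisulfite read counts
#'
#' For each CpG site and pool, draws a total read depth from a
#' negative-binomial coverage law and methylated reads from
#' `Binomial(total, baseline + slope_per_year * pool_age)` for CpGs in
#' affected regions (`baseline` alone otherwise). Pool-level methylation
#' proportions then approximate the age-group mean, as in an equal-mass
#' pooling design.
#'
#' @param design Pool design table, e.g. [pool_design_default()].
#' @param cpg_sites Data.frame of targeted CpGs with columns `feature`,
#'   `chrom`, `pos` (1-based).
#' @param baseline_meth Baseline methylation proportion per CpG (scalar or
#'   per-site vector).
#' @param slope_per_year Methylation proportion change per year at affected
#'   regions (default 5e-4, i.e. ~3.7% from age 4 to 78).
#' @param affected Character vector of affected feature names.
#' @param coverage_mean,coverage_size Negative-binomial mean and size for
#'   per-CpG read depth (defaults give a median depth near 679 reads).
#' @param seed RNG seed.
#' @return Data.frame of per-CpG per-pool counts: `chrom`, `pos`, `feature`,
#'   `pool_id`, `pool_age`, `meth_reads`, `total_reads`.
#' @export
simulate_pooled_bis <- function(design, cpg_sites,
                                baseline_meth = 0.02,
                                slope_per_year = 5e-4,
                                affected = character(),
                                coverage_mean = 679, coverage_size = 50,
                                seed = 1L) {
  stopifnot(all(c("pool_id", "mean_age") %in% names(design)),
            all(c("feature", "chrom", "pos") %in% names(cpg_sites)))
  if (any(baseline_meth < 0) || any(baseline_meth > 1)) {
    stop("baseline_meth must be a proportion in [0, 1]")
  }
  max_age <- max(design$mean_age)
  if (any(baseline_meth + slope_per_year * max_age > 1) ||
      any(baseline_meth + slope_per_year * max_age < 0)) {
    stop("methylation probability out of [0, 1] after age effect")
  }
  set.seed(seed)
  base <- rep_len(baseline_meth, nrow(cpg_sites))
  is_aff <- cpg_sites$feature %in% affected
  out <- lapply(seq_len(nrow(design)), function(k) {
    p <- base + ifelse(is_aff, slope_per_year * design$mean_age[k], 0)
    total <- stats::rnbinom(nrow(cpg_sites), mu = coverage_mean,
                            size = coverage_size) + 1L
    meth <- stats::rbinom(nrow(cpg_sites), total, p)
    data.frame(
      chrom = cpg_sites$chrom, pos = cpg_sites$pos,
      feature = cpg_sites$feature,
      pool_id = design$pool_id[k], pool_age = design$mean_age[k],
      meth_reads = meth, total_reads = total, stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Derive targeted CpG sites from simulated tRNA genes
#'
#' Places a small number of CpGs inside each gene body, matching the observed
#' scale of a median of about 6 assayable CpGs per targeted tRNA.
#'
#' @param genes Feature table.
#' @param cpgs_per_gene_range Min/max CpGs per gene (default 1-9).
#' @param seed RNG seed.
#' @return Data.frame with `feature`, `chrom`, `pos`.
#' @export
trna_cpg_sites <- function(genes, cpgs_per_gene_range = c(1, 9), seed = 1L) {
  set.seed(seed)
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    len <- genes$end[i] - genes$start[i]
    k <- sample(seq(cpgs_per_gene_range[1], cpgs_per_gene_range[2]), 1L)
    k <- min(k, floor(len / 2))
    pos <- genes$start[i] + sort(sample.int(len - 1L, k))
    data.frame(feature = genes$name[i], chrom = genes$chrom[i], pos = pos,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Write a simulated study to disk in the pipeline's input formats
#'
#' Writes the tRNA annotation BED, window table, score matrix, sample
#' metadata, planted truth and the config (seed included) so a simulated run
#' is indistinguishable, format-wise, from a real one.
#'
#' @param sim A `trna_sim` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisible named vector of written paths.
#' @export
write_simulated_study <- function(sim, dir) {
  stopifnot(inherits(sim, "trna_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genes = file.path(dir, "trna_genes.bed"),
    windows = file.path(dir, "windows.tsv"),
    scores = file.path(dir, "score_matrix.tsv"),
    samples = file.path(dir, "samples.tsv"),
    truth = file.path(dir, "truth.tsv"),
    config = file.path(dir, "sim_config.json")
  )
  write_feature_bed(sim$genes, paths[["genes"]])
  utils::write.table(sim$windows, paths[["windows"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_score_matrix(sim$scores, paths[["scores"]])
  utils::write.table(sim$samples, paths[["samples"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth_df <- data.frame(
    affected_gene = sim$truth$affected_genes,
    slope_per_year = rep_len(sim$truth$slope_per_year,
                             length(sim$truth$affected_genes)),
    stringsAsFactors = FALSE
  )
  utils::write.table(truth_df, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(unclass(sim$config), paths[["config"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
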