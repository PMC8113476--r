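#' Specify an age model
#'
#' The covariate sets mirror the four standard cross-sectional models plus
#' the longitudinal variant:
#' model 1 no covariates; model 2 batch; model 3 the four blood cell counts
#' (lymphocytes, monocytes, neutrophils, eosinophils); model 4 batch plus
#' cell counts; `"longitudinal"` adds the participant identifier as a fixed
#' effect on top of model 4.
#'
#' `direction = "meth_response"` regresses methylation on age (slope in score
#' units per year); `direction = "age_response"` regresses age on methylation
#' (slope in years per score unit). The association p-value is the partial
#' F-test for the age-methylation term either way, and a positive slope
#' always means hypermethylation with age.
#'
#' @param model_id One of `1, 2, 3, 4, "longitudinal"`.
#' @param direction `"meth_response"` (default) or `"age_response"`.
#' @return List of class `age_model_spec` with `model_id`, `direction`,
#'   `covariates`.
#' @export
age_model_spec <- function(model_id = 4, direction = "meth_response") {
  model_id <- as.character(model_id)
  cells <- c("lymphocytes", "monocytes", "neutrophils", "eosinophils")
  covariates <- switch(model_id,
    "1" = character(),
    "2" = "batch",
    "3" = cells,
    "4" = c("batch", cells),
    "longitudinal" = c("batch", cells, "participant_id"),
    stop("unknown model_id: ", model_id)
  )
  direction <- match.arg(direction, c("meth_response", "age_response"))
  structure(list(model_id = model_id, direction = direction,
                 covariates = covariates), class = "age_model_spec")
}

# build the covariate model matrix (no intercept column; categorical
# covariates one-hot with first level as reference)
.covariate_matrix <- function(samples, covariates) {
  if (length(covariates) == 0L) {
    return(matrix(numeric(0), nrow = nrow(samples), ncol = 0))
  }
  missing <- setdiff(covariates, names(samples))
  if (length(missing) > 0L) {
    stop("missing covariate columns: ", paste(missing, collapse = ", "))
  }
  df <- samples[, covariates, drop = FALSE]
  for (nm in covariates) {
    if (is.character(df[[nm]])) df[[nm]] <- factor(df[[nm]])
    if (anyNA(df[[nm]])) stop("missing values in covariate: ", nm)
    # a single-level factor carries no contrast (e.g. one batch after
    # subsetting); drop it rather than abort
    if (is.factor(df[[nm]]) && nlevels(droplevels(df[[nm]])) < 2L) {
      df[[nm]] <- NULL
    }
  }
  if (ncol(df) == 0L) {
    return(matrix(numeric(0), nrow = nrow(samples), ncol = 0))
  }
  mm <- stats::model.matrix(~ ., data = df)
  mm[, -1, drop = FALSE]
}

# precomputed fitting engine: full and reduced design share all columns but
# the association term, so one pair of QR decompositions serves every window
.make_ols_engine <- function(predictor, covar_mat) {
  n <- length(predictor)
  X_red <- cbind(`(Intercept)` = 1, covar_mat)
  X_full <- cbind(X_red, assoc = predictor)
  qr_full <- qr(X_full)
  if (qr_full$rank < ncol(X_full)) {
    keep <- qr_full$pivot[seq_len(qr_full$rank)]
    dropped <- colnames(X_full)[setdiff(seq_len(ncol(X_full)), keep)]
    stop("rank-deficient design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  qr_red <- qr(X_red)
  XtX_inv <- chol2inv(qr.R(qr_full))
  list(qr_full = qr_full, qr_red = qr_red, n = n, p_full = ncol(X_full),
       assoc_var = XtX_inv[ncol(X_full), ncol(X_full)])
}

# fit one response vector through the engine; partial F for the association
# term; flagged degenerate fit when the response has no variance
.engine_fit <- function(engine, y) {
  if (stats::var(y) == 0) {
    return(list(slope = 0, se = NA_real_, p_value = 1, flag = "zero_variance"))
  }
  res_full <- qr.resid(engine$qr_full, y)
  res_red <- qr.resid(engine$qr_red, y)
  rss_full <- sum(res_full^2)
  rss_red <- sum(res_red^2)
  df_resid <- engine$n - engine$p_full
  coefs <- qr.coef(engine$qr_full, y)
  slope <- coefs[["assoc"]]
  sigma2 <- rss_full / df_resid
  se <- sqrt(sigma2 * engine$assoc_var)
  if (rss_full <= 0) {
    # perfect fit: F statistic unbounded
    return(list(slope = slope, se = 0,
                p_value = .Machine$double.xmin, flag = "perfect_fit"))
  }
  fstat <- (rss_red - rss_full) / sigma2
  p <- stats::pf(fstat, 1, df_resid, lower.tail = FALSE)
  list(slope = slope, se = se, p_value = max(p, .Machine$double.xmin),
       flag = NA_character_)
}

#' Fit an age model to one window's methylation scores
#'
#' Ordinary least squares with the spec's fixed effects; the p-value is the
#' partial F-test comparing the model with and without the age-methylation
#' association term (for model 1 this equals the simple-regression F-test).
#' Positive slope means hypermethylation with age, in either direction.
#'
#' Zero-variance methylation (or age) yields a flagged result with slope 0
#' and p = 1 and a warning rather than an error, so batch drivers stay
#' aligned with their input.
#'
#' @param meth Numeric vector of methylation scores over samples.
#' @param samples Sample table with `age` and any covariate columns.
#' @param spec An [age_model_spec()].
#' @return One-row data.frame: `slope`, `se`, `p_value`, `flag`.
#' @export
fit_age_model <- function(meth, samples, spec = age_model_spec(1)) {
  stopifnot(inherits(spec, "age_model_spec"),
            length(meth) == nrow(samples))
  age <- samples$age
  covar <- .covariate_matrix(samples, spec$covariates)
  n_par <- ncol(covar) + 2L
  if (length(meth) < n_par + 2L) {
    stop("too few samples (", length(meth), ") for ", n_par, " parameters")
  }
  degen_age <- stats::var(age) == 0
  degen_meth <- stats::var(meth) == 0
  if (degen_age || degen_meth) {
    warning("zero-variance ", if (degen_age) "age" else "methylation",
            "; returning flagged null result")
    return(data.frame(slope = 0, se = NA_real_, p_value = 1,
                      flag = "zero_variance", stringsAsFactors = FALSE))
  }
  if (spec$direction == "meth_response") {
    engine <- .make_ols_engine(age, covar)
    fit <- .engine_fit(engine, meth)
  } else {
    engine <- .make_ols_engine(meth, covar)
    fit <- .engine_fit(engine, age)
  }
  data.frame(slope = fit$slope, se = fit$se, p_value = fit$p_value,
             flag = fit$flag, stringsAsFactors = FALSE)
}

#' Fit an age model to every window of a score matrix
#'
#' Equivalent to looping [fit_age_model()] over rows, but reuses one QR
#' decomposition of the shared design for `direction = "meth_response"`.
#' Degenerate windows are flagged, never dropped, so the output stays
#' aligned with the input rows.
#'
#' @param scores Windows-by-samples matrix; columns must match
#'   `samples$sample_id` when both are named.
#' @param samples Sample table.
#' @param spec An [age_model_spec()].
#' @return Data.frame with one row per window: `window`, `slope`, `se`,
#'   `p_value`, `flag`.
#' @export
fit_all_windows <- function(scores, samples, spec = age_model_spec(4)) {
  scores <- as.matrix(scores)
  if (nrow(scores) == 0L) {
    return(data.frame(window = character(), slope = numeric(), se = numeric(),
                      p_value = numeric(), flag = character(),
                      stringsAsFactors = FALSE))
  }
  if (!is.null(colnames(scores)) && "sample_id" %in% names(samples)) {
    if (!identical(colnames(scores), samples$sample_id)) {
      if (!all(colnames(scores) %in% samples$sample_id)) {
        stop("score matrix columns do not match sample table")
      }
      samples <- samples[match(colnames(scores), samples$sample_id), ,
                         drop = FALSE]
    }
  }
  wnames <- rownames(scores)
  if (is.null(wnames)) wnames <- as.character(seq_len(nrow(scores)))

  if (spec$direction == "meth_response" && stats::var(samples$age) > 0) {
    covar <- .covariate_matrix(samples, spec$covariates)
    engine <- .make_ols_engine(samples$age, covar)
    rows <- lapply(seq_len(nrow(scores)), function(i) {
      y <- scores[i, ]
      if (stats::var(y) == 0) {
        return(data.frame(slope = 0, se = NA_real_, p_value = 1,
                          flag = "zero_variance", stringsAsFactors = FALSE))
      }
      f <- .engine_fit(engine, y)
      data.frame(slope = f$slope, se = f$se, p_value = f$p_value,
                 flag = f$flag, stringsAsFactors = FALSE)
    })
  } else {
    rows <- lapply(seq_len(nrow(scores)), function(i) {
      withCallingHandlers(
        fit_age_model(scores[i, ], samples, spec),
        warning = function(w) invokeRestart("muffleWarning")
      )
    })
  }
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(window = wnames, stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' Longitudinal age models over revisited participants
#'
#' Retains participants with at least two samples whose ages span at least
#' `min_gap_years`, then fits the longitudinal spec (batch, blood cell
#' counts and participant identifier as fixed effects) to every window, so
#' the age effect is identified within person.
#'
#' @param scores Windows-by-samples matrix.
#' @param samples Sample table with `participant_id`.
#' @param min_gap_years Minimum within-participant age gap (default 5).
#' @param direction Passed to [age_model_spec()].
#' @return List with `results` (as [fit_all_windows()]) and `samples_used`.
#' @export
fit_longitudinal <- function(scores, samples, min_gap_years = 5,
                             direction = "meth_response") {
  stopifnot("participant_id" %in% names(samples))
  spans <- tapply(samples$age, samples$participant_id,
                  function(a) if (length(a) >= 2) diff(range(a)) else -Inf)
  keep_participants <- names(spans)[spans >= min_gap_years]
  keep <- samples$participant_id %in% keep_participants
  if (length(keep_participants) < 2L) {
    stop("no qualifying participants with >= 2 visits spanning ",
         min_gap_years, " years")
  }
  sub <- samples[keep, , drop = FALSE]
  scores_sub <- as.matrix(scores)[, match(sub$sample_id, colnames(scores)),
                                  drop = FALSE]
  spec <- age_model_spec("longitudinal", direction = direction)
  list(results = fit_all_windows(scores_sub, sub, spec), samples_used = sub)
}

#' Mixed-model likelihood-ratio test for one window
#'
#' Tests the age-methylation association while modelling family structure:
#' the null mixed model has batch and the four blood cell counts as fixed
#' effects with family id and zygosity as random intercepts; the full model
#' adds the quantile-normalised methylation score. Both are fitted by
#' maximum likelihood and compared with a chi-squared(1) likelihood-ratio
#' test. A singular random-effects fit falls back to the fixed-effects
#' partial F-test with a warning.
#'
#' @param meth Numeric methylation vector.
#' @param samples Sample table with `age`, `batch`, cell counts, `family_id`,
#'   `zygosity`.
#' @return List: `statistic`, `p_value`, `method` (`"lrt"` or
#'   `"fixed_fallback"`).
#' @export
mixed_model_lrt <- function(meth, samples) {
  stopifnot("family_id" %in% names(samples))
  if (length(unique(samples$family_id)) < 10L) {
    stop("need >= 10 families for the mixed model")
  }
  df <- data.frame(
    age = samples$age, meth = meth, batch = factor(samples$batch),
    lymphocytes = samples$lymphocytes, monocytes = samples$monocytes,
    neutrophils = samples$neutrophils, eosinophils = samples$eosinophils,
    family_id = factor(samples$family_id),
    zygosity = factor(ifelse(is.na(samples$zygosity), "none",
                             samples$zygosity))
  )
  fixed_fallback <- function() {
    warning("mixed-model fit failed; falling back to fixed-effects partial F")
    spec <- age_model_spec(4, direction = "age_response")
    r <- fit_age_model(meth, samples, spec)
    list(statistic = NA_real_, p_value = r$p_value, method = "fixed_fallback")
  }
  # boundary (zero-variance) fits are kept: the LRT remains valid there and
  # approaches the fixed-effects partial F; only a failed fit falls back
  form <- age ~ batch + lymphocytes + monocytes + neutrophils + eosinophils +
    (1 | family_id) + (1 | zygosity)
  if (nlevels(df$zygosity) < 2L) {
    # a single zygosity level carries no grouping information
    form <- age ~ batch + lymphocytes + monocytes + neutrophils +
      eosinophils + (1 | family_id)
  }
  res <- tryCatch({
    null_fit <- lme4::lmer(
      form, data = df, REML = FALSE,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE))
    full_fit <- stats::update(null_fit, . ~ . + meth)
    a <- stats::anova(null_fit, full_fit)
    list(statistic = a$Chisq[2], p_value = a[["Pr(>Chisq)"]][2],
         method = "lrt")
  }, error = function(e) fixed_fallback())
  res
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param m Number of tests; e.g. the number of autosomal tRNA features for
#'   study-wide significance, or the number of genome windows for genome-wide
#'   significance.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (missing(m) || length(m) != 1L || is.na(m) || m < 1) {
    stop("m must be a positive count")
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  alpha / m
}

#' Summarise window-level age results at tRNA gene level
#'
#' A tRNA gene is significant when any overlapping window passes the
#' threshold. Per gene, the minimum-p window is reported; ties are broken by
#' larger absolute slope, then lexicographic window name. Genes with no
#' overlapping window get a flagged "no coverage" row. A window shared by
#' two genes contributes to both.
#'
#' @param results Window results from [fit_all_windows()].
#' @param map Window-to-feature map from [map_windows_to_features()].
#' @param thresholds List with `study_wide` and `genome_wide` p cutoffs.
#' @param features Optional feature table; genes absent from `map` are then
#'   reported with `no_coverage = TRUE`.
#' @return Data.frame with one row per gene: `feature`, `best_window`,
#'   `p_value`, `slope`, `n_windows`, `direction`, `study_wide_significant`,
#'   `genome_wide_significant`, `no_coverage`.
#' @export
summarize_by_trna <- function(results, map,
                              thresholds = list(study_wide = 0.05,
                                                genome_wide = 0.05),
                              features = NULL) {
  stopifnot(all(c("window", "p_value", "slope") %in% names(results)))
  missing_windows <- setdiff(unique(map$window), results$window)
  if (length(missing_windows) > 0L) {
    stop("windows in map without results, e.g. ", missing_windows[1])
  }
  ridx <- match(map$window, results$window)
  per_gene <- split(ridx, map$feature)
  rows <- lapply(names(per_gene), function(g) {
    idx <- per_gene[[g]]
    sub <- results[idx, , drop = FALSE]
    ord <- order(sub$p_value, -abs(sub$slope), sub$window)
    best <- sub[ord[1L], , drop = FALSE]
    data.frame(
      feature = g, best_window = best$window, p_value = best$p_value,
      slope = best$slope, n_windows = nrow(sub),
      direction = ifelse(best$slope >= 0, "hyper", "hypo"),
      study_wide_significant = best$p_value < thresholds$study_wide,
      genome_wide_significant = best$p_value < thresholds$genome_wide,
      no_coverage = FALSE, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (!is.null(features)) {
    uncovered <- setdiff(features$name, out$feature)
    if (length(uncovered) > 0L) {
      out <- rbind(out, data.frame(
        feature = uncovered, best_window = NA_character_,
        p_value = NA_real_, slope = NA_real_, n_windows = 0L,
        direction = NA_character_, study_wide_significant = FALSE,
        genome_wide_significant = FALSE, no_coverage = TRUE,
        stringsAsFactors = FALSE
      ))
    }
    out <- out[match(features$name[features$name %in% out$feature],
                     out$feature), , drop = FALSE]
  } else {
    out <- out[order(out$feature), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
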