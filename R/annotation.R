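#' Read a BED file of tRNA genes (or other features)
#'
#' Reads a BED4+ file (gtRNAdb-style) into a feature table. Coordinates follow
#' the BED convention: 0-based start, half-open `[start, end)`. Columns beyond
#' the first six are ignored. Where the feature name parses as
#' `tRNA-Isotype-Anticodon-family-copy` (e.g. `tRNA-iMet-CAT-1-4`) the isotype,
#' anticodon and copy identifier are extracted into their own columns.
#'
#' @param path Path to a tab-separated BED file with at least 4 columns
#'   (chrom, start, end, name).
#' @return A data.frame with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `isotype`, `anticodon`, `copy_id`. Strand is `"."` when the file
#'   has no strand column. One row per input line, order preserved.
#' @export
read_feature_bed <- function(path) {
  if (!file.exists(path)) {
    stop("BED file not found: ", path)
  }
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(empty_feature_table())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 4L)) {
    bad <- which(n_fields < 4L)[1L]
    stop("BED parse error at line ", lineno[bad],
         ": fewer than 4 tab-separated columns")
  }
  starts <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  ends <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(starts) || anyNA(ends)) {
    bad <- which(is.na(starts) | is.na(ends))[1L]
    stop("BED parse error at line ", lineno[bad], ": non-integer coordinates")
  }
  if (any(starts < 0) || any(starts >= ends)) {
    bad <- which(starts < 0 | starts >= ends)[1L]
    stop("BED parse error at line ", lineno[bad],
         ": requires 0 <= start < end")
  }
  out <- data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    start = starts,
    end = ends,
    name = vapply(fields, `[[`, "", 4L),
    score = vapply(fields, function(f) if (length(f) >= 5L) f[[5L]] else "0", ""),
    strand = vapply(fields, function(f) if (length(f) >= 6L) f[[6L]] else ".", ""),
    stringsAsFactors = FALSE
  )
  out$strand[!out$strand %in% c("+", "-", ".")] <- "."
  parsed <- parse_trna_name(out$name)
  out$isotype <- parsed$isotype
  out$anticodon <- parsed$anticodon
  out$copy_id <- parsed$copy_id
  out
}

empty_feature_table <- function() {
  data.frame(
    chrom = character(), start = numeric(), end = numeric(),
    name = character(), score = character(), strand = character(),
    isotype = character(), anticodon = character(), copy_id = character(),
    stringsAsFactors = FALSE
  )
}

#' Parse tRNA gene names into isotype / anticodon / copy identifier
#'
#' @param name Character vector of feature names such as `tRNA-iMet-CAT-1-4`.
#' @return A data.frame with `isotype`, `anticodon`, `copy_id`; `NA` where the
#'   name does not follow the `tRNA-Isotype-Anticodon-family-copy` pattern.
#' @export
parse_trna_name <- function(name) {
  pat <- "^(?:tRNA-)?([A-Za-z]+)-([A-Za-z]{3})-([0-9]+)-([0-9]+)$"
  ok <- grepl(pat, name)
  isotype <- ifelse(ok, sub(pat, "\\1", name), NA_character_)
  anticodon <- ifelse(ok, sub(pat, "\\2", name), NA_character_)
  copy_id <- ifelse(ok,
    paste(sub(pat, "\\1", name), sub(pat, "\\2", name),
          sub(pat, "\\3", name), sub(pat, "\\4", name), sep = "-"),
    NA_character_)
  data.frame(isotype = isotype, anticodon = anticodon, copy_id = copy_id,
             stringsAsFactors = FALSE)
}

#' Write a feature table back out as BED6
#'
#' @param features Feature data.frame as returned by [read_feature_bed()].
#' @param path Output path.
#' @export
write_feature_bed <- function(features, path) {
  df <- features[, c("chrom", "start", "end", "name")]
  df$score <- if ("score" %in% names(features)) features$score else 0
  df$strand <- if ("strand" %in% names(features)) features$strand else "."
  utils::write.table(
    format(df, scientific = FALSE, trim = TRUE),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

# half-open overlap of one interval against a set; returns logical per row of set
.overlaps_any <- function(chrom, start, end, set) {
  same <- set$chrom == chrom
  any(same & set$start < end & start < set$end)
}

#' Filter features to autosomes and remove blacklist overlaps
#'
#' Keeps features whose chromosome is in `autosomes` and which share no base
#' pair with any blacklist interval (any-overlap rule under half-open
#' coordinate arithmetic). Input order is preserved. Anomalous-signal
#' blacklist regions are supplied by the user as a BED-style table.
#'
#' @param genes Feature data.frame (chrom/start/end/name columns).
#' @param blacklist Data.frame of intervals to exclude (chrom/start/end);
#'   may have zero rows.
#' @param autosomes Character vector of allowed chromosome names.
#' @return The filtered feature data.frame.
#' @export
filter_features <- function(genes, blacklist, autosomes) {
  if (nrow(genes) == 0L) return(genes)
  keep_chrom <- genes$chrom %in% autosomes
  if (is.null(blacklist) || nrow(blacklist) == 0L) {
    return(genes[keep_chrom, , drop = FALSE])
  }
  hit <- vapply(seq_len(nrow(genes)), function(i) {
    .overlaps_any(genes$chrom[i], genes$start[i], genes$end[i], blacklist)
  }, logical(1))
  genes[keep_chrom & !hit, , drop = FALSE]
}

#' Cluster tRNA genes by genomic proximity
#'
#' Single-linkage merge of genes along each chromosome, in the style of
#' `bedtools merge -d`: sorted neighbours join one group whenever the gap from
#' the end of the current group to the start of the next gene is at most
#' `max_gap`. Groups are then kept as clusters only if they contain at least
#' `min_genes` members and have a density of at least `min_density` genes per
#' megabase, where the span runs from the minimum start to the maximum end of
#' the members.
#'
#' @param genes Feature data.frame (chrom/start/end/name).
#' @param max_gap Maximum gap in bp between neighbours in one cluster
#'   (default 5e6).
#' @param min_genes Minimum number of member genes (default 5).
#' @param min_density Minimum genes per Mb over the cluster span (default 5).
#' @return Data.frame with one row per cluster: `chrom`, `span_start`,
#'   `span_end`, `n_genes`, `density_per_mb`, `members` (comma-joined names).
#' @export
cluster_trnas <- function(genes, max_gap = 5e6, min_genes = 5, min_density = 5) {
  if (max_gap <= 0 || min_genes <= 0 || min_density <= 0) {
    stop("cluster parameters must be positive")
  }
  empty <- data.frame(
    chrom = character(), span_start = numeric(), span_end = numeric(),
    n_genes = integer(), density_per_mb = numeric(), members = character(),
    stringsAsFactors = FALSE
  )
  if (nrow(genes) == 0L) return(empty)
  ord <- order(genes$chrom, genes$start, genes$end, genes$name)
  g <- genes[ord, , drop = FALSE]
  # assign group ids by walking sorted genes per chromosome
  grp <- integer(nrow(g))
  gid <- 0L
  cur_end <- -Inf
  cur_chrom <- ""
  for (i in seq_len(nrow(g))) {
    if (g$chrom[i] != cur_chrom || g$start[i] - cur_end > max_gap) {
      gid <- gid + 1L
      cur_chrom <- g$chrom[i]
      cur_end <- g$end[i]
    } else {
      cur_end <- max(cur_end, g$end[i])
    }
    grp[i] <- gid
  }
  rows <- lapply(split(seq_len(nrow(g)), grp), function(idx) {
    span_start <- min(g$start[idx])
    span_end <- max(g$end[idx])
    n <- length(idx)
    dens <- n / ((span_end - span_start) / 1e6)
    data.frame(
      chrom = g$chrom[idx[1]], span_start = span_start, span_end = span_end,
      n_genes = n, density_per_mb = dens,
      members = paste(g$name[idx], collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[out$n_genes >= min_genes & out$density_per_mb >= min_density, ,
             drop = FALSE]
  out <- out[order(out$chrom, out$span_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write tRNA clusters as a merged-interval BED file
#'
#' Each cluster becomes one BED line spanning its members, with the member
#' names comma-joined in the name column.
#'
#' @param clusters Cluster table from [cluster_trnas()].
#' @param path Output path.
#' @export
write_cluster_bed <- function(clusters, path) {
  df <- data.frame(
    chrom = clusters$chrom, start = clusters$span_start,
    end = clusters$span_end, name = clusters$members,
    stringsAsFactors = FALSE
  )
  utils::write.table(
    format(df, scientific = FALSE, trim = TRUE),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
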