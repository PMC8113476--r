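#' Generate fixed-width sliding windows over a genome
#'
#' Builds the windowed representation used for MeDIP-seq-style regional
#' methylation scores: windows of `size` bp starting at 0 and every `step` bp
#' thereafter on each chromosome. Windows extending past the chromosome end
#' are dropped rather than truncated, so every window has identical length and
#' CpG densities are directly comparable. With the defaults (500 bp windows,
#' 250 bp slide) each tRNA-sized locus (~73 bp) is covered by 2-3 windows.
#'
#' @param chrom_sizes Data.frame with columns `chrom` and `length` (bp), or a
#'   named numeric vector of chromosome lengths.
#' @param size Window width in bp (default 500).
#' @param step Slide in bp (default 250); must satisfy `0 < step <= size`.
#' @return Data.frame of windows ordered by (chrom, start) with columns
#'   `chrom`, `start`, `end`, `name` (`"chrom:start-end"`).
#' @export
make_sliding_windows <- function(chrom_sizes, size = 500, step = 250) {
  if (is.numeric(chrom_sizes) && !is.null(names(chrom_sizes))) {
    chrom_sizes <- data.frame(chrom = names(chrom_sizes),
                              length = as.numeric(chrom_sizes),
                              stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(chrom_sizes),
            all(c("chrom", "length") %in% names(chrom_sizes)))
  if (size <= 0 || step <= 0 || step > size) {
    stop("require size > 0 and 0 < step <= size")
  }
  if (anyNA(chrom_sizes$length) || any(chrom_sizes$length <= 0)) {
    stop("unknown or non-positive chromosome length")
  }
  cs <- chrom_sizes[order(chrom_sizes$chrom), , drop = FALSE]
  parts <- lapply(seq_len(nrow(cs)), function(i) {
    L <- cs$length[i]
    if (L < size) return(NULL)
    starts <- seq(0, L - size, by = step)
    data.frame(chrom = cs$chrom[i], start = starts, end = starts + size,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE)
  }
  out$name <- sprintf("%s:%d-%d", out$chrom, as.integer(out$start),
                      as.integer(out$end))
  rownames(out) <- NULL
  out
}

#' Count CpG dinucleotides in a sequence
#'
#' Counts occurrences of "CG" (case-insensitive) on the forward strand; the
#' CpG dinucleotide is strand-symmetric so this counts every CpG site once.
#'
#' @param sequence A single DNA string over A/C/G/T/N.
#' @return Integer count of CG dinucleotides.
#' @export
count_cpgs <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) stop("empty sequence")
  seq_up <- toupper(sequence)
  m <- gregexpr("CG", seq_up, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) 0L else length(m)
}

#' CpG density as a percentage of window length
#'
#' Both bases of each CpG count towards density, so 45 CpGs in a 500 bp
#' window is an 18% density: `100 * 2 * count / len`.
#'
#' @param cpg_count CpG dinucleotide count(s).
#' @param len Window length(s) in bp.
#' @return Numeric density in percent, in `[0, 100]`.
#' @export
cpg_density_pct <- function(cpg_count, len) {
  100 * 2 * cpg_count / len
}

#' Map windows to overlapping features
#'
#' Returns every (window, feature) pair sharing at least one base pair under
#' half-open arithmetic. A tRNA gene is later called significant if any
#' overlapping window is significant, so this map is the join used to lift
#' window-level results to gene level.
#'
#' @param windows Window data.frame from [make_sliding_windows()].
#' @param features Feature data.frame (chrom/start/end/name).
#' @return Data.frame with columns `window_index`, `window`, `feature`
#'   (one row per overlapping pair).
#' @export
map_windows_to_features <- function(windows, features) {
  out <- data.frame(window_index = integer(), window = character(),
                    feature = character(), stringsAsFactors = FALSE)
  if (nrow(windows) == 0L || nrow(features) == 0L) return(out)
  rows <- lapply(seq_len(nrow(features)), function(j) {
    hit <- which(windows$chrom == features$chrom[j] &
                   windows$start < features$end[j] &
                   features$start[j] < windows$end)
    if (length(hit) == 0L) return(NULL)
    data.frame(window_index = hit, window = windows$name[hit],
               feature = features$name[j], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) out else `rownames<-`(res, NULL)
}

#' Quantile-normalise a window-by-sample score matrix
#'
#' Forces every sample (column) onto the identical empirical distribution:
#' the across-sample mean of order statistics. Within-sample rank order is
#' preserved and ties receive the mean of the tied reference values. The
#' transform is idempotent. Delegates to [limma::normalizeQuantiles()].
#'
#' @param scores Numeric matrix, windows in rows, samples in columns; no
#'   missing values.
#' @return Matrix of the same dimensions and dimnames.
#' @export
quantile_normalize <- function(scores) {
  scores <- as.matrix(scores)
  if (anyNA(scores) || any(!is.finite(scores))) {
    stop("scores must be finite with no missing values")
  }
  if (ncol(scores) < 2L) stop("quantile normalisation needs >= 2 samples")
  if (nrow(scores) < 2L) return(scores)  # single window: degenerate, unchanged
  out <- limma::normalizeQuantiles(scores, ties = TRUE)
  dimnames(out) <- dimnames(scores)
  out
}

#' Read a window-by-sample score matrix from TSV
#'
#' Expects a header of sample IDs and a first column of window names in
#' `"chrom:start-end"` form.
#'
#' @param path TSV path.
#' @return Numeric matrix with window-name rownames and sample-ID colnames.
#' @export
read_score_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Write a window-by-sample score matrix as TSV
#'
#' @param scores Matrix with window-name rownames.
#' @param path Output path.
#' @export
write_score_matrix <- function(scores, path) {
  df <- data.frame(window = rownames(scores), scores, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compute per-window CpG counts from a FASTA genome
#'
#' Convenience helper for sequence-backed runs; simulation-backed runs carry
#' CpG counts directly.
#'
#' @param windows Window data.frame.
#' @param fasta_path Path to an (uncompressed) FASTA file whose names match
#'   `windows$chrom`.
#' @return `windows` with `cpg_count` and `cpg_density_pct` columns added.
#' @export
window_cpg_counts <- function(windows, fasta_path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required for FASTA-backed CpG counting")
  }
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  counts <- vapply(seq_len(nrow(windows)), function(i) {
    chrom <- windows$chrom[i]
    if (!chrom %in% names(genome)) stop("chromosome missing from FASTA: ", chrom)
    s <- as.character(Biostrings::subseq(genome[[chrom]],
                                         start = windows$start[i] + 1L,
                                         end = windows$end[i]))
    count_cpgs(s)
  }, integer(1))
  windows$cpg_count <- counts
  windows$cpg_density_pct <- cpg_density_pct(counts, windows$end - windows$start)
  windows
}
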