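# The core enrichment statistic: genes are ordered by log fold change,
# split into equally sized contiguous bins, motif hits are summed per
# bin, and the per-bin sums are Pearson-correlated with the per-bin mean
# logFC. Motifs of factors driving (or opposing) the expression change
# stand out with large |r|.

#' Bin genes by log fold change into equally sized contiguous bins
#'
#' Genes are sorted ascending by logFC (ties broken by gene label for
#' determinism) and cut into \code{n_bins} contiguous blocks. When the
#' gene count is not divisible by \code{n_bins}, the remainder genes go
#' one each to the lowest-logFC bins, so bin sizes differ by at most 1.
#'
#' @param logfc Named numeric vector, gene -> log2 fold change.
#' @param n_bins Number of bins (>= 2, and at most the number of genes).
#' @return A list of class \code{"logfc_binning"}: \code{n_bins},
#'   \code{assignment} (named integer vector of bin indices 1..n_bins),
#'   \code{bin_mean_logfc}, \code{bin_sizes}.
#' @export
bin_by_logfc <- function(logfc, n_bins = 100L) {
  n <- length(logfc)
  if (n_bins < 2) stop("n_bins must be >= 2")
  if (n < n_bins) stop("fewer genes (", n, ") than bins (", n_bins, ")")
  if (is.null(names(logfc)) || anyDuplicated(names(logfc)))
    stop("logfc must be named with unique gene ids")
  ord <- order(logfc, names(logfc), method = "radix")
  base <- n %/% n_bins
  r <- n %% n_bins
  sizes <- rep(base, n_bins)
  if (r > 0) sizes[seq_len(r)] <- base + 1L
  bins_sorted <- rep.int(seq_len(n_bins), sizes)
  assignment <- integer(n)
  assignment[ord] <- bins_sorted
  names(assignment) <- names(logfc)
  means <- as.numeric(tapply(logfc[ord], bins_sorted, mean))
  structure(list(n_bins = as.integer(n_bins), assignment = assignment,
                 bin_mean_logfc = means, bin_sizes = sizes),
            class = "logfc_binning")
}

#' Correlate per-bin motif counts with per-bin mean logFC
#'
#' Genes present in both the count matrix and the contrast are binned by
#' logFC; per motif, its counts are summed within each bin and the
#' Pearson correlation between the per-bin sums and the per-bin mean
#' logFC is recorded. If either vector is constant the correlation is
#' undefined and reported as \code{NA} (never coerced to 0).
#'
#' @param counts Integer matrix of motif hits, genes x motifs (as from
#'   \code{\link{count_motif_hits}}).
#' @param contrast A \code{"contrast_result"}, or a named numeric vector
#'   of logFC values.
#' @param n_bins Number of logFC bins (default 100).
#' @return Data frame of class \code{"motif_correlations"} with columns
#'   \code{motif_id}, \code{pearson_r}, \code{n_bins_used}; per-bin
#'   profiles are attached as attributes \code{"per_bin_counts"} (bins x
#'   motifs) and \code{"per_bin_mean_logfc"}.
#' @export
correlate_motifs <- function(counts, contrast, n_bins = 100L) {
  logfc <- if (inherits(contrast, "contrast_result"))
    stats::setNames(contrast$logFC, contrast$gene) else contrast
  common <- intersect(rownames(counts), names(logfc))
  if (length(common) == 0)
    stop("no genes shared between count matrix and contrast")
  dropped <- (nrow(counts) - length(common)) +
    (length(logfc) - length(common))
  if (dropped > 0)
    message(dropped, " gene(s) present on only one side were dropped")
  binning <- bin_by_logfc(logfc[common], n_bins)
  bin_counts <- rowsum(counts[common, , drop = FALSE],
                       group = binning$assignment)
  bin_counts <- bin_counts[order(as.integer(rownames(bin_counts))), ,
                           drop = FALSE]
  x <- binning$bin_mean_logfc
  r <- apply(bin_counts, 2, function(y) {
    if (stats::sd(y) == 0 || stats::sd(x) == 0) NA_real_ else
      stats::cor(y, x)
  })
  out <- data.frame(motif_id = colnames(counts), pearson_r = unname(r),
                    n_bins_used = as.integer(n_bins),
                    stringsAsFactors = FALSE)
  attr(out, "per_bin_counts") <- bin_counts
  attr(out, "per_bin_mean_logfc") <- x
  attr(out, "n_genes_used") <- length(common)
  class(out) <- c("motif_correlations", "data.frame")
  out
}

#' Rank motifs by correlation
#'
#' Sorts motifs by Pearson r descending (undefined correlations last,
#' ties broken by motif id) and attaches the rank index used as the x
#' axis of the motif-vs-r scatter.
#'
#' @param correlations A \code{"motif_correlations"} data frame.
#' @return Data frame with columns \code{motif_rank}, \code{motif_id},
#'   \code{pearson_r}, \code{n_bins_used}.
#' @export
rank_motifs <- function(correlations) {
  ord <- order(-correlations$pearson_r,
               correlations$motif_id, na.last = TRUE, method = "radix")
  out <- correlations[ord, , drop = FALSE]
  out <- data.frame(motif_rank = seq_len(nrow(out)), out,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write motif correlations as a tab-delimited table
#' @param correlations A \code{"motif_correlations"} or ranked table.
#' @param path Output path.
#' @export
write_motif_correlations <- function(correlations, path) {
  utils::write.table(correlations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
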