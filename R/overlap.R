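# Gene-set overlap stage: threshold-based gene sets from contrast
# results, the exact hypergeometric upper tail computed in log space,
# and pairwise overlap analysis with Venn region counts.

#' Rule defining a threshold gene set
#'
#' Membership uses strict inequalities, as thresholds of the form
#' "logFC > 1, P < 0.05" are printed: \code{direction = "up"} keeps
#' \code{logFC > logfc_threshold}, \code{"down"} keeps
#' \code{logFC < -logfc_threshold}; a p-value cut (raw or adjusted) is
#' optional.
#'
#' @param direction \code{"up"} or \code{"down"}.
#' @param logfc_threshold Non-negative log2 magnitude.
#' @param p_threshold Optional p-value cut in (0, 1]; \code{NULL} for
#'   none.
#' @param p_kind Which p-value the cut applies to: \code{"adjusted"}
#'   (default) or \code{"raw"}.
#' @return A list of class \code{"gene_set_rule"}.
#' @export
gene_set_rule <- function(direction = c("up", "down"), logfc_threshold,
                          p_threshold = NULL,
                          p_kind = c("adjusted", "raw")) {
  direction <- match.arg(direction)
  p_kind <- match.arg(p_kind)
  if (logfc_threshold < 0) stop("logfc_threshold must be >= 0")
  if (!is.null(p_threshold) && (p_threshold <= 0 || p_threshold > 1))
    stop("p_threshold must lie in (0, 1]")
  structure(list(direction = direction, logfc_threshold = logfc_threshold,
                 p_threshold = p_threshold, p_kind = p_kind),
            class = "gene_set_rule")
}

#' Extract a gene set from a contrast result by thresholding
#'
#' @param contrast A \code{"contrast_result"}.
#' @param rule A \code{\link{gene_set_rule}}.
#' @param label Label for the resulting set.
#' @return A list of class \code{"gene_set"} with elements \code{label},
#'   \code{members}, \code{rule}, \code{contrast}.
#' @export
define_gene_set <- function(contrast, rule, label) {
  if (nrow(contrast) == 0) stop("contrast result is empty")
  keep <- if (rule$direction == "up")
    contrast$logFC > rule$logfc_threshold
  else
    contrast$logFC < -rule$logfc_threshold
  if (!is.null(rule$p_threshold)) {
    p <- if (rule$p_kind == "adjusted") contrast$p_adj else contrast$p_raw
    keep <- keep & p < rule$p_threshold
  }
  structure(list(label = label, members = unique(contrast$gene[keep]),
                 rule = rule,
                 contrast = attr(contrast, "contrast")),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d genes (%s logFC threshold %g%s)\n",
              x$label, length(x$members), x$rule$direction,
              x$rule$logfc_threshold,
              if (is.null(x$rule$p_threshold)) "" else
                sprintf(", %s p < %g", x$rule$p_kind, x$rule$p_threshold)))
  invisible(x)
}

#' Exact hypergeometric upper-tail probability
#'
#' \code{P(X >= k)} for \code{X ~ Hypergeometric(N, K, n)}: drawing
#' \code{n} elements without replacement from a universe of \code{N} of
#' which \code{K} are marked. Terms are computed in log space via
#' log-gamma and accumulated from the tail, so probabilities are
#' accurate down to the smallest representable magnitudes (~1e-300).
#'
#' @param N Universe size.
#' @param K Size of the marked class.
#' @param n Draw size.
#' @param k Observed overlap.
#' @return The upper-tail probability.
#' @export
hypergeometric_upper_tail <- function(N, K, n, k) {
  if (K > N || n > N || k < 0 || K < 0 || n < 0)
    stop("inconsistent sizes: need 0 <= K, n <= N and k >= 0")
  if (k > min(K, n)) stop("k cannot exceed min(K, n)")
  if (k <= 0) return(1)
  x <- seq.int(k, min(K, n))
  lg <- lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)
  m <- max(lg)
  # sum smallest-first (the tail end) to limit rounding loss
  exp(m) * sum(exp(rev(lg) - m))
}

#' Pairwise overlap analysis of gene sets with Venn region counts
#'
#' For every pair of sets, reports sizes, overlap, expectation
#' \code{K n / N} and the exact hypergeometric upper-tail p-value with
#' \code{N} the universe size. For up to three sets, all Venn region
#' cardinalities are returned. Members outside the universe are clipped
#' with a warning.
#'
#' @param sets List of \code{\link{define_gene_set}} objects.
#' @param universe Character vector of all genes tested.
#' @return A list of class \code{"overlap_analysis"}: \code{pairs} (data
#'   frame with \code{set_a}, \code{set_b}, \code{N}, \code{K}, \code{n},
#'   \code{k}, \code{expected_k}, \code{p_hyper}), \code{venn} (named
#'   integer vector of disjoint region counts, \code{NULL} for > 3
#'   sets), and \code{universe_size}.
#' @export
overlap_analysis <- function(sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("universe is empty")
  labels <- vapply(sets, function(s) s$label, character(1))
  members <- lapply(sets, function(s) {
    outside <- setdiff(s$members, universe)
    if (length(outside))
      warning(length(outside), " member(s) of set '", s$label,
              "' are outside the universe and were clipped")
    intersect(s$members, universe)
  })
  N <- length(universe)
  combos <- utils::combn(seq_along(sets), 2)
  pairs <- do.call(rbind, lapply(seq_len(ncol(combos)), function(j) {
    a <- combos[1, j]; b <- combos[2, j]
    K <- length(members[[a]]); n <- length(members[[b]])
    k <- length(intersect(members[[a]], members[[b]]))
    data.frame(set_a = labels[a], set_b = labels[b], N = N, K = K, n = n,
               k = k, expected_k = K * n / N,
               p_hyper = hypergeometric_upper_tail(N, K, n, k),
               stringsAsFactors = FALSE)
  }))
  venn <- NULL
  if (length(sets) <= 3) {
    inset <- vapply(members, function(m) universe %in% m,
                    logical(length(universe)))
    if (is.null(dim(inset))) inset <- matrix(inset, nrow = 1)
    pattern <- apply(inset, 1, function(row)
      if (!any(row)) "none" else paste(labels[row], collapse = "&"))
    lvls <- c(unlist(lapply(seq_along(sets), function(m)
      utils::combn(labels, m, paste, collapse = "&", simplify = TRUE))))
    venn <- table(factor(pattern, levels = lvls))
    venn <- stats::setNames(as.integer(venn), names(venn))
  }
  structure(list(pairs = pairs, venn = venn, universe_size = N),
            class = "overlap_analysis")
}

#' Write the pairwise overlap report as a tab-delimited table
#'
#' p-values are printed in scientific notation with 6 significant
#' digits.
#'
#' @param oa An \code{"overlap_analysis"}.
#' @param path Output path.
#' @export
write_overlap_report <- function(oa, path) {
  tab <- oa$pairs
  tab$p_hyper <- formatC(tab$p_hyper, format = "e", digits = 5)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
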