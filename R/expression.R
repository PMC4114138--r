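# Differential-expression stage: expression-matrix container and I/O,
# low-expression filtering, per-gene probe collapse, the empirical-Bayes
# moderated t-test, Benjamini-Hochberg correction, and time-course
# contrasts of every later time point against baseline.

#' Construct an expression matrix with sample annotations
#'
#' @param values Numeric matrix, features x samples, log2 scale, with
#'   unique rownames (feature ids) and colnames (sample ids).
#' @param samples Data frame with columns \code{sample_id},
#'   \code{condition}, \code{time_h}, \code{replicate}; one row per
#'   matrix column.
#' @return A list of class \code{"expression_matrix"} with elements
#'   \code{values} and \code{samples}.
#' @export
expression_matrix <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (nrow(values) > 0 &&
      (is.null(rownames(values)) || anyDuplicated(rownames(values))))
    stop("feature ids must be present and unique")
  if (any(!is.finite(values)))
    stop("all expression values must be finite")
  req <- c("sample_id", "condition", "time_h", "replicate")
  if (!all(req %in% names(samples)))
    stop("sample sheet must have columns: ", paste(req, collapse = ", "))
  if (nrow(samples) != ncol(values))
    stop("sample sheet rows must match matrix columns")
  samples <- samples[match(colnames(values), samples$sample_id), ]
  if (any(is.na(samples$sample_id)))
    stop("every matrix column must appear in the sample sheet")
  rownames(samples) <- NULL
  structure(list(values = values, samples = samples),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("time points (h):",
      paste(sort(unique(x$samples$time_h)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read a tab-delimited expression matrix and its sample sheet
#'
#' The matrix file has a header row, feature ids in the first column and
#' one numeric column per sample; the sample sheet maps each sample id to
#' condition, time and replicate. Row order is preserved.
#'
#' @param matrix_path,sample_sheet_path Input paths.
#' @return An \code{\link{expression_matrix}}.
#' @export
read_expression_table <- function(matrix_path, sample_sheet_path) {
  tab <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate feature id(s) in ", matrix_path, ": ",
         paste(utils::head(dup, 5), collapse = ", "))
  vals <- tab[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1]
      stop(sprintf("non-numeric expression value at row %d, column '%s'",
                   bad, names(vals)[j]))
    }
  }
  values <- as.matrix(vals)
  rownames(values) <- ids
  sheet <- utils::read.delim(sample_sheet_path, stringsAsFactors = FALSE)
  orphans <- setdiff(colnames(values), sheet$sample_id)
  if (length(orphans))
    stop("sample(s) missing from sample sheet: ",
         paste(orphans, collapse = ", "))
  expression_matrix(values, sheet)
}

#' Filter features with very low expression
#'
#' Keeps features whose value is at least \code{min_value} in at least a
#' fraction \code{min_fraction} of samples. The defaults drop features
#' that sit below the 20th percentile of the pooled value distribution in
#' every sample, i.e. features that are low everywhere.
#'
#' @param em An \code{\link{expression_matrix}}.
#' @param min_value Log2 threshold; default the 20th percentile of all
#'   values.
#' @param min_fraction Required fraction of samples at or above
#'   \code{min_value}, in [0, 1].
#' @return A filtered \code{\link{expression_matrix}}; row order kept.
#' @export
filter_low_expression <- function(em, min_value = NULL, min_fraction = 1) {
  if (min_fraction < 0 || min_fraction > 1)
    stop("min_fraction must lie in [0, 1]")
  if (is.null(min_value))
    min_value <- stats::quantile(em$values, 0.2, names = FALSE)
  keep <- rowMeans(em$values >= min_value) >= min_fraction
  if (!any(keep)) warning("no features survive the expression filter")
  expression_matrix(em$values[keep, , drop = FALSE], em$samples)
}

#' Collapse probe-level features to one row per gene
#'
#' For each gene the most informative feature is retained: the one with
#' the largest interquartile range across samples (ties broken by the
#' lexicographically smallest feature id). Unmapped features are dropped
#' with a message.
#'
#' @param em An \code{\link{expression_matrix}} of probe-level features.
#' @param feature_to_gene Named character vector mapping feature id to
#'   gene symbol.
#' @return An \code{\link{expression_matrix}} with gene symbols as row
#'   names.
#' @export
collapse_to_genes <- function(em, feature_to_gene) {
  if (length(feature_to_gene) == 0) stop("feature_to_gene mapping is empty")
  feats <- rownames(em$values)
  gene <- unname(feature_to_gene[feats])
  drop_n <- sum(is.na(gene))
  if (drop_n > 0)
    message(drop_n, " unmapped feature(s) dropped during gene collapse")
  keep <- !is.na(gene)
  vals <- em$values[keep, , drop = FALSE]
  gene <- gene[keep]
  iqr <- apply(vals, 1, stats::IQR)
  ord <- order(gene, -iqr, rownames(vals), method = "radix")
  sel <- ord[!duplicated(gene[ord])]
  sel <- sort(sel)  # preserve original row order
  out <- vals[sel, , drop = FALSE]
  rownames(out) <- gene[sel]
  expression_matrix(out, em$samples)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validating wrapper around \code{stats::p.adjust(method = "BH")}:
#' sort ascending, take \code{adj_(i) = min_{j >= i} m p_(j) / j}, cap at
#' 1, return in input order.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must be finite and lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Moderation hyperparameters for the moderated t-test
#'
#' @param d0 Prior degrees of freedom (may be \code{Inf} for complete
#'   shrinkage, or 0 to disable moderation).
#' @param s0_sq Prior variance, (log2)^2 units.
#' @param estimated_from_data Flag recording how the prior was obtained.
#' @return A list of class \code{"moderation_params"}.
#' @export
moderation_params <- function(d0, s0_sq, estimated_from_data = FALSE) {
  if (!(d0 >= 0)) stop("d0 must be >= 0 (possibly Inf)")
  if (!(s0_sq > 0)) stop("s0_sq must be > 0")
  structure(list(d0 = d0, s0_sq = s0_sq,
                 estimated_from_data = estimated_from_data),
            class = "moderation_params")
}

# Inverse of trigamma by Newton iteration on 1/trigamma (monotone convex),
# used by the moment estimator of the prior degrees of freedom.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Estimate moderation hyperparameters by the moment method
#'
#' Fits the scaled-F marginal model of the empirical-Bayes moderated
#' t-test by matching the first two moments of \code{log(s_g^2)}: with
#' \code{e_g = log(s_g^2) - digamma(d_g/2) + log(d_g/2)},
#' \code{E[e] = log(s0^2) - digamma(d0/2) + log(d0/2)} and
#' \code{Var[e] = trigamma(d_g/2) + trigamma(d0/2)}; \code{d0} is
#' recovered through the inverse trigamma. When the excess variance is
#' non-positive, \code{d0 = Inf} (all genes share \code{s0^2}).
#'
#' @param s2 Per-gene residual variances (zeros are excluded from the
#'   fit).
#' @param df Residual degrees of freedom (scalar, shared by all genes).
#' @return A \code{\link{moderation_params}}.
#' @export
estimate_moderation <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) stop("need at least two positive variances to estimate the prior")
  e <- log(s2[ok]) - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(mean(e))
  }
  moderation_params(d0 = d0, s0_sq = s0_sq, estimated_from_data = TRUE)
}

#' Empirical-Bayes moderated t-test between two sample groups
#'
#' Per gene: \code{logFC = mean(B) - mean(A)}; pooled residual variance
#' \code{s_g^2} with \code{d_g = nA + nB - 2} degrees of freedom;
#' posterior variance \code{(d0 s0^2 + d_g s_g^2) / (d0 + d_g)};
#' \code{t = logFC / (s_tilde sqrt(1/nA + 1/nB))}; two-sided p from the t
#' distribution with \code{d0 + d_g} df; BH adjustment across genes.
#' When \code{params} is absent the prior is estimated from the data by
#' \code{\link{estimate_moderation}}. Forcing \code{d0 = 0} reproduces
#' the ordinary pooled-variance t-test; \code{d0 = Inf} uses \code{s0^2}
#' for every gene.
#'
#' @param em An \code{\link{expression_matrix}}.
#' @param groupA,groupB Disjoint character vectors of sample ids, each of
#'   size >= 2. \code{logFC} is B minus A.
#' @param params Optional \code{\link{moderation_params}}.
#' @param contrast Label stored with the result.
#' @return A data frame of class \code{"contrast_result"} with columns
#'   \code{gene}, \code{logFC}, \code{t_mod}, \code{df_total},
#'   \code{p_raw}, \code{p_adj}, \code{mean_expr}; the moderation
#'   parameters used are attached as attribute \code{"moderation"}.
#' @export
moderated_t_test <- function(em, groupA, groupB, params = NULL,
                             contrast = "B_vs_A") {
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("each group needs at least 2 samples")
  if (length(intersect(groupA, groupB)) > 0)
    stop("groups must be disjoint")
  missing <- setdiff(c(groupA, groupB), colnames(em$values))
  if (length(missing))
    stop("sample(s) not in matrix: ", paste(missing, collapse = ", "))
  A <- em$values[, groupA, drop = FALSE]
  B <- em$values[, groupB, drop = FALSE]
  nA <- ncol(A); nB <- ncol(B)
  mA <- rowMeans(A); mB <- rowMeans(B)
  logfc <- mB - mA
  d_g <- nA + nB - 2
  ssA <- rowSums((A - mA)^2)
  ssB <- rowSums((B - mB)^2)
  s2 <- (ssA + ssB) / d_g
  if (is.null(params)) {
    if (all(s2 <= 0)) {
      message("all residual variances are zero; using fallback prior ",
              "(d0 = 4, s0_sq = 0.01)")
      params <- moderation_params(d0 = 4, s0_sq = 0.01)
    } else {
      params <- estimate_moderation(s2, d_g)
    }
  }
  d0 <- params$d0; s0_sq <- params$s0_sq
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
    (d0 * s0_sq + d_g * s2) / (d0 + d_g)
  se <- sqrt(s2_post * (1 / nA + 1 / nB))
  t_mod <- ifelse(se > 0, logfc / se, ifelse(logfc == 0, 0, sign(logfc) * Inf))
  df_total <- d0 + d_g
  p_raw <- 2 * stats::pt(-abs(t_mod), df = df_total)
  res <- data.frame(gene = rownames(em$values), logFC = logfc,
                    t_mod = t_mod, df_total = df_total, p_raw = p_raw,
                    p_adj = bh_adjust(p_raw),
                    mean_expr = rowMeans(cbind(A, B)),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "contrast") <- contrast
  attr(res, "moderation") <- params
  class(res) <- c("contrast_result", "data.frame")
  res
}

#' Differential expression of every later time point against baseline
#'
#' @param em An \code{\link{expression_matrix}} whose sample sheet has a
#'   \code{time_h} column.
#' @param baseline_time Baseline time in hours (default 0).
#' @param params Optional shared \code{\link{moderation_params}};
#'   estimated per contrast when absent.
#' @return Named list of \code{"contrast_result"} objects, one per later
#'   time point, named by that time in hours; BH correction is applied
#'   within each contrast.
#' @export
timecourse_contrasts <- function(em, baseline_time = 0, params = NULL) {
  times <- em$samples$time_h
  if (!baseline_time %in% times)
    stop("baseline time ", baseline_time, " h not present in sample sheet")
  base_samples <- em$samples$sample_id[times == baseline_time]
  later <- sort(unique(times[times > baseline_time]))
  if (length(later) == 0) stop("no time points later than baseline")
  out <- lapply(later, function(t) {
    moderated_t_test(em,
                     groupA = base_samples,
                     groupB = em$samples$sample_id[times == t],
                     params = params,
                     contrast = sprintf("%gh_vs_%gh", t, baseline_time))
  })
  names(out) <- as.character(later)
  out
}

#' Write a contrast result as a tab-delimited table
#' @param cr A \code{"contrast_result"}.
#' @param path Output path.
#' @export
write_contrast_result <- function(cr, path) {
  utils::write.table(cr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
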