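# Promoter annotation stage: parsers for UCSC-dialect gene-model
# (refGene-like) and conserved-TFBS (tfbsConsSites-like) tables,
# strand-aware upstream promoter windows merged per gene, motif-hit
# counting per promoter, and per-position information content of a
# position weight matrix (sequence-logo support).
#
# All genomic coordinates are 0-based half-open, as in UCSC table dumps.

# UCSC dumps optionally carry a leading integer "bin" column; detect it
# by checking whether the first column is entirely numeric.
detect_bin_column <- function(tab) {
  first <- as.character(tab[[1]])
  length(first) > 0 && !any(is.na(suppressWarnings(as.numeric(first))))
}

#' Read gene models from a refGene-dialect table
#'
#' Expects a tab-delimited file without header: an optional leading
#' numeric bin column (auto-detected), then \code{name}, \code{chrom},
#' \code{strand}, \code{txStart}, \code{txEnd}, and the gene symbol
#' (\code{name2}) either in full refGene position 12 or as the last
#' column of a short fixture. Rows with \code{txStart >= txEnd} or an
#' unparseable strand are rejected with a warning giving the count.
#'
#' @param path Input path.
#' @return Data frame of class \code{"gene_models"} with columns
#'   \code{transcript_id}, \code{gene_symbol}, \code{chrom},
#'   \code{strand}, \code{tx_start}, \code{tx_end}.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("gene model file not found: ", path)
  empty <- data.frame(transcript_id = character(0),
                      gene_symbol = character(0), chrom = character(0),
                      strand = character(0), tx_start = integer(0),
                      tx_end = integer(0), stringsAsFactors = FALSE)
  class(empty) <- c("gene_models", "data.frame")
  if (file.size(path) == 0) return(empty)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (detect_bin_column(tab)) tab <- tab[, -1, drop = FALSE]
  if (ncol(tab) < 6)
    stop("refGene dialect needs >= 6 columns (after optional bin)")
  sym_col <- if (ncol(tab) >= 12) 12L else ncol(tab)
  out <- data.frame(transcript_id = tab[[1]], gene_symbol = tab[[sym_col]],
                    chrom = tab[[2]], strand = tab[[3]],
                    tx_start = suppressWarnings(as.integer(tab[[4]])),
                    tx_end = suppressWarnings(as.integer(tab[[5]])),
                    stringsAsFactors = FALSE)
  bad <- !(out$strand %in% c("+", "-")) | is.na(out$tx_start) |
    is.na(out$tx_end) | out$tx_start >= out$tx_end
  if (any(bad))
    warning(sum(bad), " gene model row(s) rejected (bad strand or ",
            "txStart >= txEnd)")
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Read conserved TFBS records from a tfbsConsSites-dialect table
#'
#' Tab-delimited, no header: optional leading bin column, then
#' \code{chrom}, \code{chromStart}, \code{chromEnd}, \code{name} (the
#' motif identifier, e.g. \code{"V$FOXO1_01"}, kept verbatim),
#' \code{score}, \code{strand}. Rows with \code{start >= end} are
#' rejected with a warning.
#'
#' @param path Input path.
#' @return Data frame of class \code{"tfbs_sites"} with columns
#'   \code{chrom}, \code{start}, \code{end}, \code{motif_id},
#'   \code{score}, \code{strand}.
#' @export
read_tfbs_sites <- function(path) {
  if (!file.exists(path)) stop("TFBS file not found: ", path)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), motif_id = character(0),
                      score = numeric(0), strand = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("tfbs_sites", "data.frame")
  if (file.size(path) == 0) return(empty)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (detect_bin_column(tab)) tab <- tab[, -1, drop = FALSE]
  if (ncol(tab) < 6)
    stop("tfbsConsSites dialect needs >= 6 columns (after optional bin)")
  out <- data.frame(chrom = tab[[1]],
                    start = suppressWarnings(as.integer(tab[[2]])),
                    end = suppressWarnings(as.integer(tab[[3]])),
                    motif_id = tab[[4]],
                    score = suppressWarnings(as.numeric(tab[[5]])),
                    strand = tab[[6]], stringsAsFactors = FALSE)
  bad <- is.na(out$start) | is.na(out$end) | out$start >= out$end |
    out$motif_id == ""
  if (any(bad))
    warning(sum(bad), " TFBS row(s) rejected (empty motif id or ",
            "start >= end)")
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tfbs_sites", "data.frame")
  out
}

#' Strand-aware upstream promoter windows, merged per gene
#'
#' Per transcript the window is \code{[txStart - upstream_bp, txStart)}
#' on the + strand and \code{[txEnd, txEnd + upstream_bp)} on the -
#' strand (the TSS of a - strand transcript is \code{txEnd}; UCSC stores
#' \code{txStart < txEnd} regardless of strand). The lower bound is
#' clipped at 0. Windows of transcripts sharing a gene symbol on the same
#' chromosome are merged into a union of intervals; with
#' \code{merge = "first"} only the first transcript of each gene is used.
#'
#' @param models A \code{"gene_models"} data frame.
#' @param upstream_bp Window length upstream of the TSS (default 1000).
#' @param merge \code{"union"} (default) or \code{"first"}.
#' @return Data frame of class \code{"promoter_windows"} with one row per
#'   disjoint interval: \code{gene_symbol}, \code{chrom}, \code{start},
#'   \code{end}, \code{strand} (\code{"."} when transcripts of a gene
#'   disagree).
#' @export
promoter_windows <- function(models, upstream_bp = 1000L,
                             merge = c("union", "first")) {
  merge <- match.arg(merge)
  if (upstream_bp <= 0) stop("upstream_bp must be > 0")
  if (merge == "first")
    models <- models[!duplicated(models$gene_symbol), , drop = FALSE]
  plus <- models$strand == "+"
  w_start <- ifelse(plus, models$tx_start - upstream_bp, models$tx_end)
  w_end <- w_start + upstream_bp
  w_start <- pmax(w_start, 0L)  # clip windows that would cross position 0
  keep <- w_end > w_start
  df <- data.frame(gene_symbol = models$gene_symbol[keep],
                   chrom = models$chrom[keep], start = w_start[keep],
                   end = w_end[keep], strand = models$strand[keep],
                   stringsAsFactors = FALSE)
  parts <- split(df, paste(df$gene_symbol, df$chrom, sep = "\r"))
  merged <- lapply(parts, function(p) {
    ir <- IRanges::reduce(IRanges::IRanges(start = p$start + 1L,
                                           end = p$end))
    strand <- if (length(unique(p$strand)) == 1L) p$strand[1] else "."
    data.frame(gene_symbol = p$gene_symbol[1], chrom = p$chrom[1],
               start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
               strand = strand, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$gene_symbol, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("promoter_windows", "data.frame")
  out
}

#' Count motif hits in promoter windows
#'
#' By the default midpoint rule a site is assigned to a gene when
#' \code{floor((start + end) / 2)} falls inside one of the gene's
#' intervals on the matching chromosome, so each site counts at most once
#' per gene regardless of its length; \code{"contained"} requires the
#' whole site inside one interval and \code{"any"} any overlap. A site
#' may count toward several genes when windows of different genes
#' overlap. Site strand is ignored.
#'
#' @param windows A \code{"promoter_windows"} data frame.
#' @param sites A \code{"tfbs_sites"} data frame.
#' @param rule Membership rule: \code{"midpoint"} (default),
#'   \code{"contained"} or \code{"any"}.
#' @return Integer matrix of counts, genes x motif ids (sorted unique
#'   motif ids of \code{sites}).
#' @export
count_motif_hits <- function(windows, sites,
                             rule = c("midpoint", "contained", "any")) {
  rule <- match.arg(rule)
  genes <- unique(windows$gene_symbol)
  motifs <- sort(unique(sites$motif_id))
  counts <- matrix(0L, length(genes), length(motifs),
                   dimnames = list(genes, motifs))
  if (nrow(sites) == 0 || nrow(windows) == 0) return(counts)
  for (chr in intersect(unique(windows$chrom), unique(sites$chrom))) {
    w <- windows[windows$chrom == chr, , drop = FALSE]
    s <- sites[sites$chrom == chr, , drop = FALSE]
    win_ir <- IRanges::IRanges(start = w$start + 1L, end = w$end)
    site_ir <- switch(rule,
      midpoint = {
        mid <- floor((s$start + s$end) / 2)
        IRanges::IRanges(start = mid + 1L, width = 1L)
      },
      IRanges::IRanges(start = s$start + 1L, end = s$end))
    type <- if (rule == "contained") "within" else "any"
    hits <- IRanges::findOverlaps(site_ir, win_ir, type = type)
    if (length(hits) == 0) next
    # a gene's merged window may be several disjoint intervals and an
    # "any"-overlap site can touch more than one; count each (site, gene)
    # pair once
    pairs <- unique(data.frame(site = S4Vectors::queryHits(hits),
                               gene = w$gene_symbol[S4Vectors::subjectHits(hits)],
                               motif = s$motif_id[S4Vectors::queryHits(hits)],
                               stringsAsFactors = FALSE))
    tab <- table(factor(pairs$gene, levels = genes),
                 factor(pairs$motif, levels = motifs))
    counts <- counts + matrix(as.integer(tab), nrow = length(genes))
  }
  counts
}

#' Per-position information content of a position weight matrix
#'
#' For each position \code{j}, \code{IC_j = 2 + sum_b p_jb log2 p_jb}
#' (with \code{0 log2 0 = 0}), in bits; 0 for a uniform column, 2 for a
#' deterministic one. This is the column height used in sequence logos.
#'
#' @param pwm Numeric matrix with 4 rows (A, C, G, T) and one column per
#'   motif position; every column must sum to 1 within 1e-9.
#' @return Numeric vector of bits per position, values in [0, 2].
#' @export
pwm_information_content <- function(pwm) {
  pwm <- as.matrix(pwm)
  if (nrow(pwm) != 4) stop("pwm must have 4 rows (A, C, G, T)")
  if (any(pwm < 0)) stop("pwm probabilities must be >= 0")
  cs <- colSums(pwm)
  if (any(abs(cs - 1) > 1e-9))
    stop("pwm column(s) do not sum to 1: ",
         paste(which(abs(cs - 1) > 1e-9), collapse = ", "))
  plogp <- pwm * log2(pwm)
  plogp[pwm == 0] <- 0
  2 + colSums(plogp)
}

#' Export promoter windows as BED
#'
#' Columns: chrom, start, end, gene symbol, score 0, strand (0-based
#' half-open, one line per disjoint interval).
#'
#' @param windows A \code{"promoter_windows"} data frame.
#' @param path Output path.
#' @export
write_promoter_bed <- function(windows, path) {
  bed <- data.frame(windows$chrom, windows$start, windows$end,
                    windows$gene_symbol, 0L, windows$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a motif count matrix as a tab-delimited table
#' @param counts Integer matrix, genes x motifs.
#' @param path Output path.
#' @export
write_motif_counts <- function(counts, path) {
  tab <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
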