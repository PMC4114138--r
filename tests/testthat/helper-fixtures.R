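# Shared fixture builders and independent brute-force oracles used
# across the suite. Oracles here deliberately avoid the package's own
# code paths.

# Small expression matrix with explicit values and a two-time design.
toy_expression <- function(values, times = NULL) {
  if (is.null(times)) times <- rep(0, ncol(values))
  samples <- data.frame(sample_id = colnames(values),
                        condition = ifelse(times == 0, "baseline",
                                           "knockdown"),
                        time_h = times,
                        replicate = ave(times, times, FUN = seq_along),
                        stringsAsFactors = FALSE)
  expression_matrix(values, samples)
}

# Quadratic brute-force motif counter over all (window, site) pairs.
brute_force_counts <- function(windows, sites,
                               rule = c("midpoint", "contained", "any")) {
  rule <- match.arg(rule)
  genes <- unique(windows$gene_symbol)
  motifs <- sort(unique(sites$motif_id))
  counts <- matrix(0L, length(genes), length(motifs),
                   dimnames = list(genes, motifs))
  for (i in seq_along(genes)) {
    w <- windows[windows$gene_symbol == genes[i], , drop = FALSE]
    for (j in seq_len(nrow(sites))) {
      s <- sites[j, ]
      hit <- FALSE
      for (v in seq_len(nrow(w))) {
        if (w$chrom[v] != s$chrom) next
        inside <- switch(rule,
          midpoint = {
            mid <- floor((s$start + s$end) / 2)
            mid >= w$start[v] && mid < w$end[v]
          },
          contained = s$start >= w$start[v] && s$end <= w$end[v],
          any = s$start < w$end[v] && s$end > w$start[v])
        if (inside) { hit <- TRUE; break }
      }
      if (hit) {
        m <- match(s$motif_id, motifs)
        counts[i, m] <- counts[i, m] + 1L
      }
    }
  }
  counts
}

# Exact hypergeometric upper tail by literal enumeration of all draws
# of size n from a universe of size N (feasible only for small N).
enumerate_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Exact two-sided rank-sum p by literal enumeration of group-label
# assignments.
enumerate_rank_sum <- function(a, b) {
  na <- length(a); n <- na + length(b)
  r <- rank(c(a, b))
  W <- sum(r[seq_len(na)])
  W_all <- utils::combn(n, na, function(s) sum(r[s]))
  min(1, 2 * min(mean(W_all <= W + 1e-9), mean(W_all >= W - 1e-9)))
}

# Random promoter windows and sites on a couple of chromosomes,
# including overlapping windows of different genes.
random_landscape <- function(n_genes = 20, n_sites = 200, seed = 1) {
  set.seed(seed)
  chroms <- c("chr1", "chr2")
  gene_chrom <- sample(chroms, n_genes, replace = TRUE)
  starts <- sample(0:5000, n_genes, replace = TRUE)
  windows <- data.frame(gene_symbol = sprintf("G%02d", seq_len(n_genes)),
                        chrom = gene_chrom, start = starts,
                        end = starts + sample(200:1000, n_genes, TRUE),
                        strand = sample(c("+", "-"), n_genes, TRUE),
                        stringsAsFactors = FALSE)
  class(windows) <- c("promoter_windows", "data.frame")
  s_start <- sample(0:6000, n_sites, replace = TRUE)
  sites <- data.frame(chrom = sample(chroms, n_sites, replace = TRUE),
                      start = s_start,
                      end = s_start + sample(5:30, n_sites, TRUE),
                      motif_id = sample(sprintf("V$M%02d", 1:8), n_sites,
                                        replace = TRUE),
                      score = 800, strand = ".",
                      stringsAsFactors = FALSE)
  class(sites) <- c("tfbs_sites", "data.frame")
  list(windows = windows, sites = sites)
}
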