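# Seeded generators for the three synthetic inputs the pipeline consumes:
# a regulator-knockdown expression time course with planted activated and
# repressed gene groups, a promoter/TFBS landscape in which designated
# motifs are Poisson-enriched in a planted regulon, and two-arm exponential
# tumor growth curves with lognormal measurement noise.
#
# Each generator seeds its own RNG stream from its config, so adding or
# reordering calls to one generator never perturbs the output of another.

#' Configuration for the synthetic knockdown time course
#'
#' Describes a time-resolved expression experiment after silencing a
#' regulator: a fraction of genes falls (they were activated by the
#' regulator), a fraction rises (they were repressed), the rest are null.
#' The planted log2 effect at time \code{t} is
#' \code{effect_logfc * effect_ramp(t)}; the default ramp is linear from 0
#' at baseline to 1 at the final time point.
#'
#' @param seed Integer seed for this generator's RNG stream.
#' @param n_genes Number of genes.
#' @param time_points_h Strictly increasing measurement times in hours,
#'   starting at 0 (the pre-knockdown baseline).
#' @param n_replicates_per_point Replicate arrays per time point.
#' @param frac_activated,frac_repressed Fractions of genes activated
#'   (falling on knockdown) and repressed (rising) by the regulator;
#'   their sum must not exceed 1.
#' @param effect_logfc Magnitude of the planted log2 fold change at the
#'   final time point.
#' @param effect_ramp Function mapping time in hours to the fraction of
#'   the full effect in [0, 1], with \code{effect_ramp(0) == 0}.
#' @param noise_sd Standard deviation of i.i.d. Gaussian noise, log2 units.
#' @param baseline_mean,baseline_sd Mean and sd of per-gene baseline
#'   log2 expression.
#' @param frac_regulon Fraction of the repressed genes assigned to the
#'   planted regulon (the targets of the candidate downstream factor).
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       time_points_h = c(0, 18, 36, 53, 72),
                       n_replicates_per_point = 2L,
                       frac_activated = 0.1,
                       frac_repressed = 0.1,
                       effect_logfc = 1.5,
                       effect_ramp = NULL,
                       noise_sd = 0.5,
                       baseline_mean = 8,
                       baseline_sd = 2,
                       frac_regulon = 1) {
  if (is.null(effect_ramp)) {
    t_final <- max(time_points_h)
    effect_ramp <- function(t) t / t_final
  }
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              time_points_h = as.numeric(time_points_h),
              n_replicates_per_point = as.integer(n_replicates_per_point),
              frac_activated = frac_activated,
              frac_repressed = frac_repressed,
              effect_logfc = effect_logfc, effect_ramp = effect_ramp,
              noise_sd = noise_sd, baseline_mean = baseline_mean,
              baseline_sd = baseline_sd, frac_regulon = frac_regulon)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$frac_activated < 0 || cfg$frac_repressed < 0 ||
      cfg$frac_activated + cfg$frac_repressed > 1)
    stop("invalid config: frac_activated + frac_repressed must lie in [0, 1]")
  if (cfg$noise_sd < 0) stop("invalid config: noise_sd must be >= 0")
  tp <- cfg$time_points_h
  if (length(tp) < 2 || any(diff(tp) <= 0) || tp[1] != 0)
    stop("invalid config: time_points_h must be strictly increasing and start at 0")
  if (abs(cfg$effect_ramp(0)) > 1e-12)
    stop("invalid config: effect_ramp(0) must be 0")
  if (cfg$frac_regulon < 0 || cfg$frac_regulon > 1)
    stop("invalid config: frac_regulon must lie in [0, 1]")
  if (cfg$n_genes < 1 || cfg$n_replicates_per_point < 1)
    stop("invalid config: n_genes and n_replicates_per_point must be positive")
  invisible(cfg)
}

#' Simulate a knockdown expression time course
#'
#' Generates a log2 expression matrix (genes x samples) under the model
#' \code{value = baseline(g) + sign(g) * effect_logfc * effect_ramp(t) +
#' N(0, noise_sd)}, where \code{sign} is -1 for genes activated by the
#' silenced regulator (they fall on knockdown), +1 for repressed genes
#' (they rise), and 0 for null genes. Identical config and seed give
#' bit-identical output.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return A list with elements \code{expression} (an
#'   \code{\link{expression_matrix}}) and \code{truth}, the planted ground
#'   truth: \code{activated_genes}, \code{repressed_genes},
#'   \code{regulon_genes} (a subset of the repressed genes),
#'   \code{planted_motif_ids} (filled by
#'   \code{\link{simulate_promoter_landscape}}), and \code{trajectory},
#'   the true per-gene log2 fold change at each time point.
#' @export
simulate_timecourse <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_genes
  genes <- sprintf("gene%05d", seq_len(n))
  n_act <- round(cfg$frac_activated * n)
  n_rep <- round(cfg$frac_repressed * n)
  activated <- genes[seq_len(n_act)]
  repressed <- genes[seq_len(n_rep) + n_act]
  sgn <- c(rep(-1, n_act), rep(1, n_rep), rep(0, n - n_act - n_rep))

  tp <- cfg$time_points_h
  reps <- cfg$n_replicates_per_point
  ramp <- vapply(tp, cfg$effect_ramp, numeric(1))
  sample_time <- rep(tp, each = reps)
  sample_rep <- rep(seq_len(reps), times = length(tp))
  sample_id <- sprintf("t%03d_r%d", as.integer(round(sample_time)), sample_rep)

  baseline <- stats::rnorm(n, cfg$baseline_mean, cfg$baseline_sd)
  true_fc <- outer(sgn * cfg$effect_logfc, ramp)  # genes x time points
  dimnames(true_fc) <- list(genes, as.character(tp))
  signal <- baseline + true_fc[, match(sample_time, tp), drop = FALSE]
  noise <- matrix(stats::rnorm(n * length(sample_id), 0, cfg$noise_sd),
                  nrow = n)
  values <- signal + noise
  dimnames(values) <- list(genes, sample_id)

  samples <- data.frame(
    sample_id = sample_id,
    condition = ifelse(sample_time == 0, "baseline", "knockdown"),
    time_h = sample_time,
    replicate = sample_rep,
    stringsAsFactors = FALSE
  )
  regulon <- repressed[seq_len(round(cfg$frac_regulon * length(repressed)))]
  truth <- list(activated_genes = activated,
                repressed_genes = repressed,
                regulon_genes = regulon,
                planted_motif_ids = character(0),
                trajectory = true_fc,
                seed = cfg$seed)
  list(expression = expression_matrix(values, samples), truth = truth)
}

#' Configuration for the synthetic promoter/TFBS landscape
#'
#' Motif-hit counts per promoter are Poisson: rate
#' \code{lambda_planted} for planted motifs in regulon genes,
#' \code{lambda_background} everywhere else. Genes are laid out on one
#' chromosome with alternating strands and TSS spacing large enough that
#' upstream windows of neighbouring genes never overlap.
#'
#' @param seed Integer seed.
#' @param n_motifs Total number of distinct motif identifiers, planted
#'   ones included.
#' @param planted_motif_ids Motif identifiers enriched in the regulon.
#' @param lambda_background,lambda_planted Poisson rates per promoter;
#'   \code{lambda_planted >= lambda_background >= 0}.
#' @param upstream_bp Promoter window length upstream of the TSS.
#' @param gene_spacing_bp Distance between consecutive TSS slots; must
#'   exceed twice \code{upstream_bp}.
#' @param chrom_name Chromosome label for all synthetic features.
#' @param transcripts_per_gene Transcripts emitted per gene; values above
#'   one add TSS-shifted isoforms to exercise per-gene window merging.
#' @param site_width_bp Width of each emitted TFBS record.
#' @return A list of class \code{"promoter_sim_config"}.
#' @export
promoter_sim_config <- function(seed = 1L,
                                n_motifs = 51L,
                                planted_motif_ids = "V$FOXO1_01",
                                lambda_background = 1,
                                lambda_planted = 3,
                                upstream_bp = 1000L,
                                gene_spacing_bp = 10000L,
                                chrom_name = "chrS",
                                transcripts_per_gene = 1L,
                                site_width_bp = 12L) {
  cfg <- list(seed = as.integer(seed), n_motifs = as.integer(n_motifs),
              planted_motif_ids = as.character(planted_motif_ids),
              lambda_background = lambda_background,
              lambda_planted = lambda_planted,
              upstream_bp = as.integer(upstream_bp),
              gene_spacing_bp = as.integer(gene_spacing_bp),
              chrom_name = chrom_name,
              transcripts_per_gene = as.integer(transcripts_per_gene),
              site_width_bp = as.integer(site_width_bp))
  class(cfg) <- "promoter_sim_config"
  if (cfg$lambda_background < 0 || cfg$lambda_planted < cfg$lambda_background)
    stop("invalid config: need lambda_planted >= lambda_background >= 0")
  if (cfg$upstream_bp <= 0) stop("invalid config: upstream_bp must be > 0")
  if (cfg$gene_spacing_bp <= 2L * cfg$upstream_bp)
    stop("invalid config: gene_spacing_bp must exceed 2 * upstream_bp")
  if (cfg$n_motifs < length(cfg$planted_motif_ids))
    stop("invalid config: n_motifs smaller than number of planted motifs")
  if (cfg$site_width_bp < 1 || cfg$site_width_bp > cfg$upstream_bp)
    stop("invalid config: site_width_bp must lie in [1, upstream_bp]")
  cfg
}

#' Simulate a promoter landscape with planted motif enrichment
#'
#' For every gene in \code{truth} a gene model is laid out (alternating
#' strands, well-separated TSS), and for every (gene, motif) pair a count
#' \code{c(g, m) ~ Poisson(lambda)} of TFBS records is placed wholly
#' inside the gene's upstream window. Enrichment is planted at the count
#' level only; no sequence is generated.
#'
#' @param truth Ground truth from \code{\link{simulate_timecourse}}.
#' @param cfg A \code{\link{promoter_sim_config}}.
#' @return A list with \code{gene_models} and \code{tfbs_sites} data
#'   frames (the dialects read by \code{\link{read_gene_models}} and
#'   \code{\link{read_tfbs_sites}}), \code{planted_counts} (the genes x
#'   motifs count matrix actually drawn), and \code{truth} with
#'   \code{planted_motif_ids} filled in.
#' @export
simulate_promoter_landscape <- function(truth, cfg) {
  set.seed(cfg$seed)
  genes <- rownames(truth$trajectory)
  if (anyDuplicated(genes)) stop("truth gene ids must be unique")
  n <- length(genes)
  n_bg <- cfg$n_motifs - length(cfg$planted_motif_ids)
  motifs <- c(cfg$planted_motif_ids,
              if (n_bg > 0) sprintf("V$BG%04d_01", seq_len(n_bg)))

  in_regulon <- genes %in% truth$regulon_genes
  is_planted <- motifs %in% cfg$planted_motif_ids
  lambda <- matrix(cfg$lambda_background, n, length(motifs))
  lambda[in_regulon, is_planted] <- cfg$lambda_planted
  counts <- matrix(stats::rpois(n * length(motifs), lambda),
                   n, length(motifs), dimnames = list(genes, motifs))

  # layout: each gene occupies a slot [i*spacing, (i+1)*spacing); the
  # transcript body sits 2*upstream into the slot so the upstream window
  # never leaves it and never goes below 0.
  up <- cfg$upstream_bp
  strand <- rep(c("+", "-"), length.out = n)
  slot <- (seq_len(n) - 1L) * cfg$gene_spacing_bp
  tx_start <- slot + 2L * up
  tx_end <- tx_start + up
  # promoter window of the primary transcript, in 0-based half-open coords
  win_start <- ifelse(strand == "+", tx_start - up, tx_end)
  win_end <- win_start + up

  gm <- data.frame(name = sprintf("NM_%06d", seq_len(n)),
                   chrom = cfg$chrom_name, strand = strand,
                   txStart = tx_start, txEnd = tx_end, name2 = genes,
                   stringsAsFactors = FALSE)
  if (cfg$transcripts_per_gene > 1L) {
    # extra isoforms with TSS shifted downstream by < upstream_bp, so the
    # merged per-gene window is a strict superset of the primary window
    for (k in seq_len(cfg$transcripts_per_gene - 1L)) {
      shift <- as.integer(floor(up * k / cfg$transcripts_per_gene))
      iso <- gm[seq_len(n), ]
      iso$name <- sprintf("NM_%06d.%d", seq_len(n), k)
      iso$txStart <- ifelse(strand == "+", tx_start + shift, tx_start)
      iso$txEnd <- ifelse(strand == "+", tx_end, tx_end - shift)
      gm <- rbind(gm, iso)
    }
  }

  total <- sum(counts)
  gi <- rep(rep(seq_len(n), times = length(motifs)), times = as.vector(counts))
  mi <- rep(rep(seq_along(motifs), each = n), times = as.vector(counts))
  w <- cfg$site_width_bp
  # sites placed uniformly, wholly inside the primary promoter window
  offset <- floor(stats::runif(total) * (up - w + 1))
  site_start <- win_start[gi] + as.integer(offset)
  tfbs <- data.frame(chrom = rep(cfg$chrom_name, total),
                     chromStart = site_start,
                     chromEnd = site_start + w,
                     name = motifs[mi],
                     score = as.integer(floor(stats::runif(total, 300, 1001))),
                     strand = sample(c("+", "-"), total, replace = TRUE),
                     stringsAsFactors = FALSE)
  truth$planted_motif_ids <- cfg$planted_motif_ids
  list(gene_models = gm, tfbs_sites = tfbs, planted_counts = counts,
       truth = truth)
}

#' Configuration for synthetic two-arm tumor growth curves
#'
#' @param seed Integer seed.
#' @param n_per_arm Animals per arm (control and treated).
#' @param days Measurement days, non-negative and increasing.
#' @param v0_mm3 Common initial tumor volume, mm^3.
#' @param growth_rate_per_day Exponential growth rate of the control arm.
#' @param treatment_multiplier Ratio in (0, 1] applied to the growth rate
#'   of the treated arm (1 = no effect).
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   measurement noise.
#' @return A list of class \code{"growth_sim_config"}.
#' @export
growth_sim_config <- function(seed = 1L,
                              n_per_arm = 10L,
                              days = seq(0, 21, by = 3),
                              v0_mm3 = 100,
                              growth_rate_per_day = 0.15,
                              treatment_multiplier = 0.5,
                              noise_cv = 0.2) {
  cfg <- list(seed = as.integer(seed), n_per_arm = as.integer(n_per_arm),
              days = as.numeric(days), v0_mm3 = v0_mm3,
              growth_rate_per_day = growth_rate_per_day,
              treatment_multiplier = treatment_multiplier,
              noise_cv = noise_cv)
  class(cfg) <- "growth_sim_config"
  if (cfg$v0_mm3 <= 0) stop("invalid config: v0_mm3 must be > 0")
  if (any(cfg$days < 0) || any(diff(cfg$days) <= 0))
    stop("invalid config: days must be non-negative and increasing")
  if (cfg$noise_cv < 0) stop("invalid config: noise_cv must be >= 0")
  if (cfg$treatment_multiplier <= 0 || cfg$treatment_multiplier > 1)
    stop("invalid config: treatment_multiplier must lie in (0, 1]")
  if (cfg$n_per_arm < 2) stop("invalid config: need >= 2 animals per arm")
  cfg
}

#' Simulate two-arm exponential tumor growth curves
#'
#' \code{volume(i, t) = v0 * exp(rate_i * t) * LogNormal(0, sigma)} with
#' \code{rate_i} scaled by \code{treatment_multiplier} in the treated arm
#' and \code{sigma = sqrt(log(1 + noise_cv^2))}.
#'
#' @param cfg A \code{\link{growth_sim_config}}.
#' @return A long-format data frame of class \code{"growth_curves"} with
#'   columns \code{animal_id}, \code{group} (\code{"control"} /
#'   \code{"treated"}), \code{day}, \code{volume_mm3}.
#' @export
simulate_growth_curves <- function(cfg) {
  set.seed(cfg$seed)
  sigma <- sqrt(log(1 + cfg$noise_cv^2))
  ids <- c(sprintf("C%02d", seq_len(cfg$n_per_arm)),
           sprintf("T%02d", seq_len(cfg$n_per_arm)))
  grp <- rep(c("control", "treated"), each = cfg$n_per_arm)
  rate <- ifelse(grp == "treated",
                 cfg$growth_rate_per_day * cfg$treatment_multiplier,
                 cfg$growth_rate_per_day)
  out <- expand.grid(day = cfg$days, idx = seq_along(ids),
                     KEEP.OUT.ATTRS = FALSE)
  mu <- cfg$v0_mm3 * exp(rate[out$idx] * out$day)
  noise <- if (sigma > 0) exp(stats::rnorm(nrow(out), 0, sigma)) else 1
  gc <- data.frame(animal_id = ids[out$idx], group = grp[out$idx],
                   day = out$day, volume_mm3 = mu * noise,
                   stringsAsFactors = FALSE)
  gc <- gc[order(gc$animal_id, gc$day), ]
  rownames(gc) <- NULL
  class(gc) <- c("growth_curves", "data.frame")
  gc
}

#' Write an expression matrix and its sample sheet to tab-delimited files
#'
#' @param em An \code{\link{expression_matrix}}.
#' @param matrix_path Output path for the matrix (first column
#'   \code{feature_id}, then one column per sample).
#' @param sample_sheet_path Output path for the sample sheet
#'   (\code{sample_id}, \code{condition}, \code{time_h}, \code{replicate}).
#' @export
write_expression_table <- function(em, matrix_path, sample_sheet_path) {
  tab <- data.frame(feature_id = rownames(em$values), em$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(em$samples, sample_sheet_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(matrix_path, sample_sheet_path))
}

#' Write synthetic gene models in the refGene dialect
#'
#' @param gene_models Data frame with columns \code{name}, \code{chrom},
#'   \code{strand}, \code{txStart}, \code{txEnd}, \code{name2}.
#' @param path Output path.
#' @param bin Emit a leading numeric bin column (as UCSC dumps do).
#' @export
write_gene_models <- function(gene_models, path, bin = FALSE) {
  cols <- c("name", "chrom", "strand", "txStart", "txEnd", "name2")
  tab <- gene_models[, cols]
  if (bin) tab <- cbind(bin = 0L, tab)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write synthetic TFBS records in the tfbsConsSites dialect
#'
#' @param tfbs_sites Data frame with columns \code{chrom},
#'   \code{chromStart}, \code{chromEnd}, \code{name}, \code{score},
#'   \code{strand}.
#' @param path Output path.
#' @param bin Emit a leading numeric bin column.
#' @export
write_tfbs_sites <- function(tfbs_sites, path, bin = FALSE) {
  cols <- c("chrom", "chromStart", "chromEnd", "name", "score", "strand")
  tab <- tfbs_sites[, cols]
  if (bin) tab <- cbind(bin = 0L, tab)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write growth curves as a long-format tab-delimited table
#' @param gc A \code{"growth_curves"} data frame.
#' @param path Output path.
#' @export
write_growth_table <- function(gc, path) {
  utils::write.table(gc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize the planted ground truth as JSON
#' @param truth Truth list from the simulators.
#' @param path Output path.
#' @export
write_truth_json <- function(truth, path) {
  out <- truth
  out$trajectory <- list(genes = rownames(truth$trajectory),
                         time_h = colnames(truth$trajectory),
                         logfc = unname(as.data.frame(truth$trajectory)))
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
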