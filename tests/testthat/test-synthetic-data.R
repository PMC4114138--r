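test_that("time-course generator is deterministic and honours the planted effect", {
  cfg <- sim_config(seed = 11, n_genes = 60, noise_sd = 0,
                    effect_logfc = 2, frac_activated = 0.2,
                    frac_repressed = 0.2)
  sim1 <- simulate_timecourse(cfg)
  sim2 <- simulate_timecourse(cfg)
  expect_identical(sim1$expression$values, sim2$expression$values)
  expect_identical(sim1$truth, sim2$truth)

  vals <- sim1$expression$values
  samp <- sim1$expression$samples
  final <- samp$sample_id[samp$time_h == 72]
  base <- samp$sample_id[samp$time_h == 0]
  diff <- rowMeans(vals[, final, drop = FALSE]) -
    rowMeans(vals[, base, drop = FALSE])
  expect_equal(unname(diff[sim1$truth$repressed_genes]),
               rep(2, length(sim1$truth$repressed_genes)))
  expect_equal(unname(diff[sim1$truth$activated_genes]),
               rep(-2, length(sim1$truth$activated_genes)))
  null_genes <- setdiff(rownames(vals), c(sim1$truth$repressed_genes,
                                          sim1$truth$activated_genes))
  expect_equal(unname(diff[null_genes]), rep(0, length(null_genes)))
  # group structure
  expect_length(intersect(sim1$truth$activated_genes,
                          sim1$truth$repressed_genes), 0)
  expect_true(all(sim1$truth$regulon_genes %in% sim1$truth$repressed_genes))
})

test_that("time-course config invariants are enforced", {
  expect_error(sim_config(frac_activated = 0.7, frac_repressed = 0.5),
               "frac_activated")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(time_points_h = c(18, 36)), "time_points_h")
  expect_error(sim_config(time_points_h = c(0, 36, 36)), "time_points_h")
  expect_error(sim_config(effect_ramp = function(t) 0.5), "effect_ramp")
})

test_that("promoter landscape emits exactly the drawn counts, wholly inside windows", {
  cfg <- sim_config(seed = 3, n_genes = 40, frac_repressed = 0.25)
  truth <- simulate_timecourse(cfg)$truth
  pcfg <- promoter_sim_config(seed = 5, n_motifs = 6,
                              lambda_background = 0.8, lambda_planted = 4)
  land <- simulate_promoter_landscape(truth, pcfg)
  # conservation: one emitted record per drawn count
  expect_equal(nrow(land$tfbs_sites), sum(land$planted_counts))
  # brute-force rescan of emitted records against the promoter windows
  gm <- land$gene_models
  windows <- promoter_windows(
    structure(data.frame(transcript_id = gm$name, gene_symbol = gm$name2,
                         chrom = gm$chrom, strand = gm$strand,
                         tx_start = gm$txStart, tx_end = gm$txEnd,
                         stringsAsFactors = FALSE),
              class = c("gene_models", "data.frame")),
    upstream_bp = pcfg$upstream_bp)
  sites <- data.frame(chrom = land$tfbs_sites$chrom,
                      start = land$tfbs_sites$chromStart,
                      end = land$tfbs_sites$chromEnd,
                      motif_id = land$tfbs_sites$name,
                      stringsAsFactors = FALSE)
  rescan <- brute_force_counts(windows, sites, rule = "contained")
  drawn <- land$planted_counts[rownames(rescan), colnames(rescan)]
  expect_equal(rescan, drawn)
})

test_that("without a planted rate difference no motif-count enrichment exists", {
  cfg <- sim_config(seed = 21, n_genes = 50, frac_repressed = 0.3)
  truth <- simulate_timecourse(cfg)$truth
  pcfg <- promoter_sim_config(seed = 22, n_motifs = 4,
                              lambda_background = 2, lambda_planted = 2)
  land <- simulate_promoter_landscape(truth, pcfg)
  in_reg <- rownames(land$planted_counts) %in% truth$regulon_genes
  planted <- land$planted_counts[, land$truth$planted_motif_ids]
  # same Poisson rate everywhere: regulon mean close to background mean
  expect_lt(abs(mean(planted[in_reg]) - mean(planted[!in_reg])), 0.5)
})

test_that("zero background rate yields no planted-motif records outside the regulon", {
  cfg <- sim_config(seed = 8, n_genes = 30, frac_repressed = 0.2,
                    frac_regulon = 0.5)
  truth <- simulate_timecourse(cfg)$truth
  pcfg <- promoter_sim_config(seed = 9, n_motifs = 3,
                              lambda_background = 0, lambda_planted = 3)
  land <- simulate_promoter_landscape(truth, pcfg)
  outside <- !rownames(land$planted_counts) %in% truth$regulon_genes
  expect_true(all(land$planted_counts[outside, ] == 0))
  bg_cols <- setdiff(colnames(land$planted_counts),
                     land$truth$planted_motif_ids)
  expect_true(all(land$planted_counts[, bg_cols] == 0))
})

test_that("growth generator matches the closed form without noise", {
  cfg <- growth_sim_config(seed = 1, n_per_arm = 3, days = c(0, 5, 10),
                           v0_mm3 = 100, growth_rate_per_day = 0.1,
                           treatment_multiplier = 1, noise_cv = 0)
  gc <- simulate_growth_curves(cfg)
  # both arms identical deterministic exponentials
  ctrl <- gc[gc$group == "control" & gc$day == 10, "volume_mm3"]
  trt <- gc[gc$group == "treated" & gc$day == 10, "volume_mm3"]
  expect_equal(ctrl, rep(100 * exp(1), 3))
  expect_equal(trt, ctrl)
  # determinism with noise
  cfg2 <- growth_sim_config(seed = 4, noise_cv = 0.3)
  expect_identical(simulate_growth_curves(cfg2),
                   simulate_growth_curves(cfg2))
})

test_that("written synthetic tables round-trip through the readers", {
  cfg <- sim_config(seed = 13, n_genes = 12, n_replicates_per_point = 2)
  sim <- simulate_timecourse(cfg)
  land <- simulate_promoter_landscape(sim$truth,
                                      promoter_sim_config(seed = 14,
                                                          n_motifs = 3))
  tmp <- withr::local_tempdir()
  write_expression_table(sim$expression, file.path(tmp, "em.tsv"),
                         file.path(tmp, "ss.tsv"))
  em <- read_expression_table(file.path(tmp, "em.tsv"),
                              file.path(tmp, "ss.tsv"))
  expect_equal(em$values, sim$expression$values)
  expect_equal(em$samples$time_h, sim$expression$samples$time_h)

  write_gene_models(land$gene_models, file.path(tmp, "gm.txt"))
  gm <- read_gene_models(file.path(tmp, "gm.txt"))
  expect_equal(nrow(gm), nrow(land$gene_models))
  expect_equal(gm$gene_symbol, land$gene_models$name2)

  write_tfbs_sites(land$tfbs_sites, file.path(tmp, "tfbs.txt"))
  sites <- read_tfbs_sites(file.path(tmp, "tfbs.txt"))
  expect_equal(nrow(sites), nrow(land$tfbs_sites))
  expect_equal(sites$start, land$tfbs_sites$chromStart)

  gcs <- simulate_growth_curves(growth_sim_config(seed = 15))
  write_growth_table(gcs, file.path(tmp, "growth.tsv"))
  back <- read_growth_table(file.path(tmp, "growth.tsv"))
  expect_equal(back$volume_mm3, gcs$volume_mm3)
})
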