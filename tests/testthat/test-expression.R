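test_that("expression table I/O round-trips and rejects malformed input", {
  vals <- matrix(c(1.5, 2, 3, 4.25, 5, 6), nrow = 3,
                 dimnames = list(c("1007_s_at", "1053_at", "117_at"),
                                 c("s1", "s2")))
  em <- toy_expression(vals, times = c(0, 0))
  tmp <- withr::local_tempdir()
  mp <- file.path(tmp, "m.tsv"); sp <- file.path(tmp, "s.tsv")
  write_expression_table(em, mp, sp)
  back <- read_expression_table(mp, sp)
  expect_equal(back$values, vals)

  # duplicated feature id is named in the error
  dup <- readLines(mp)
  writeLines(c(dup, dup[2]), file.path(tmp, "dup.tsv"))
  expect_error(read_expression_table(file.path(tmp, "dup.tsv"), sp),
               "1007_s_at")

  # orphan sample (in matrix, missing from sheet) is listed
  sheet <- utils::read.delim(sp)
  utils::write.table(sheet[sheet$sample_id != "s2", ],
                     file.path(tmp, "short.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  expect_error(read_expression_table(mp, file.path(tmp, "short.tsv")),
               "s2")

  # non-numeric cell is located
  bad <- sub("^1053_at\t2", "1053_at\toops", dup)
  writeLines(bad, file.path(tmp, "bad.tsv"))
  expect_error(read_expression_table(file.path(tmp, "bad.tsv"), sp),
               "non-numeric")
})

test_that("low-expression filter applies the value/fraction rule exactly", {
  vals <- rbind(a = c(7, 7, 7, 7), b = c(5, 5, 5, 5), c = c(5, 7, 7, 7),
                d = c(5, 5, 7, 7), e = c(6, 6, 6, 5.9))
  colnames(vals) <- paste0("s", 1:4)
  em <- toy_expression(vals)
  # brute-force evaluation of the rule at min_value 6, min_fraction 0.5
  keep <- apply(vals, 1, function(v) mean(v >= 6) >= 0.5)
  got <- filter_low_expression(em, min_value = 6, min_fraction = 0.5)
  expect_identical(rownames(got$values), names(keep)[keep])
  # min_fraction 0 keeps everything
  expect_equal(nrow(filter_low_expression(em, 6, 0)$values), 5)
  # all-low feature removed under the strict default fraction
  expect_false("b" %in%
    rownames(filter_low_expression(em, min_value = 6)$values))
  expect_warning(filter_low_expression(em, min_value = 100), "no features")
})

test_that("gene collapse keeps the most variable probe set with deterministic ties", {
  vals <- rbind(p1 = c(1, 1, 1, 1),        # constant, gene A
                p2 = c(1, 5, 2, 8),        # varying, gene A
                p3 = c(0, 2, 4, 6),        # gene B
                p4 = c(0, 1, 2, 3),        # gene B, smaller IQR
                p6 = c(3, 3, 3, 3),        # gene C tie (both constant)...
                p5 = c(4, 4, 4, 4))        # ...breaks to smaller id p5
  colnames(vals) <- paste0("s", 1:4)
  em <- toy_expression(vals)
  map <- c(p1 = "A", p2 = "A", p3 = "B", p4 = "B", p5 = "C", p6 = "C")
  got <- collapse_to_genes(em, map)
  # brute-force maximal-IQR choice per gene
  expected <- sapply(split(names(map), map), function(fs) {
    iqr <- apply(vals[fs, , drop = FALSE], 1, IQR)
    fs <- sort(fs)
    fs[which.max(iqr[fs])]
  })
  expect_equal(got$values[sort(names(expected)), ],
               unname(vals[expected[sort(names(expected))], ]),
               ignore_attr = TRUE)
  expect_setequal(rownames(got$values), c("A", "B", "C"))
  # single-probe gene passes through unchanged
  expect_equal(unname(got$values["B", ]), unname(vals["p3", ]))
  # unmapped features dropped with a message; empty map errors
  expect_message(collapse_to_genes(em, map[-1]), "unmapped")
  expect_error(collapse_to_genes(em, character(0)), "empty")
})

test_that("moderated t matches hand evaluation of the formula chain", {
  vals <- rbind(g1 = c(5, 7, 9, 13),   # logFC 5, pooled s2 5
                g2 = c(4, 6, 4, 6))    # identical group means
  colnames(vals) <- c("a1", "a2", "b1", "b2")
  em <- toy_expression(vals)
  res <- moderated_t_test(em, c("a1", "a2"), c("b1", "b2"),
                          params = moderation_params(d0 = 4, s0_sq = 1))
  # frozen hand computation: s2_post = (4 + 2*5)/6, t = 5/sqrt(s2_post), df 6
  expect_equal(res$logFC, c(5, 0))
  expect_equal(res$t_mod[1], 3.2732683535, tolerance = 1e-10)
  expect_equal(res$df_total, c(6, 6))
  expect_equal(res$p_raw[1], 0.0169647363, tolerance = 1e-8)
  expect_equal(res$t_mod[2], 0)
  expect_equal(res$p_raw[2], 1)
  expect_true(all(res$p_adj >= res$p_raw))
})

test_that("d0 = 0 reproduces the ordinary pooled t and d0 = Inf full shrinkage", {
  set.seed(42)
  vals <- matrix(rnorm(50 * 6), nrow = 50,
                 dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:6)))
  em <- toy_expression(vals)
  A <- paste0("s", 1:3); B <- paste0("s", 4:6)
  res0 <- moderated_t_test(em, A, B,
                           params = moderation_params(0, s0_sq = 1))
  classic <- apply(vals, 1, function(v) {
    t.test(v[4:6], v[1:3], var.equal = TRUE)$statistic
  })
  expect_equal(res0$t_mod, unname(classic), tolerance = 1e-12)

  resInf <- moderated_t_test(em, A, B,
                             params = moderation_params(Inf, s0_sq = 2))
  se <- sqrt(2 * (1 / 3 + 1 / 3))
  expect_equal(resInf$t_mod, res0$logFC / se, tolerance = 1e-12)
})

test_that("estimated prior agrees with the independent empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(7)
  n <- 400
  vals <- matrix(rnorm(n * 8, sd = rep(sqrt(1 / rgamma(n, 3, 3)), 8)),
                 nrow = n, dimnames = list(sprintf("g%03d", 1:n),
                                           paste0("s", 1:8)))
  em <- toy_expression(vals)
  A <- paste0("s", 1:4); B <- paste0("s", 5:8)
  res <- moderated_t_test(em, A, B)
  params <- attr(res, "moderation")
  s2 <- apply(vals, 1, function(v) {
    (sum((v[1:4] - mean(v[1:4]))^2) + sum((v[5:8] - mean(v[5:8]))^2)) / 6
  })
  fit <- limma::fitFDist(s2, df1 = 6)
  expect_equal(params$d0, fit$df2, tolerance = 1e-6)
  expect_equal(params$s0_sq, fit$scale, tolerance = 1e-6)
  # and the whole chain agrees with the reference moderated t
  design <- cbind(1, rep(c(0, 1), each = 4))
  lf <- limma::eBayes(limma::lmFit(vals, design))
  expect_equal(res$t_mod, unname(lf$t[, 2]), tolerance = 1e-8)
  expect_equal(res$p_raw, unname(lf$p.value[, 2]), tolerance = 1e-8)
})

test_that("moderated t is calibrated under the null", {
  cfg <- sim_config(seed = 101, n_genes = 10000, frac_activated = 0,
                    frac_repressed = 0, noise_sd = 0.5,
                    n_replicates_per_point = 3,
                    time_points_h = c(0, 36))
  sim <- simulate_timecourse(cfg)
  res <- timecourse_contrasts(sim$expression)[["36"]]
  expect_gte(mean(res$p_raw < 0.05), 0.04)
  expect_lte(mean(res$p_raw < 0.05), 0.06)
})

test_that("BH adjustment follows the step-up definition and is monotone", {
  expect_equal(bh_adjust(c(0.005, 0.04, 0.03)), c(0.015, 0.04, 0.04))
  expect_equal(bh_adjust(rep(0.02, 5)), rep(0.02, 5))
  expect_equal(bh_adjust(0.7), 0.7)
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  set.seed(1)
  for (i in 1:5) {
    p <- runif(40)
    adj <- bh_adjust(p)
    # direct step-up formula
    m <- length(p)
    o <- order(p)
    direct <- numeric(m)
    direct[o] <- rev(cummin(rev(pmin(1, m * p[o] / seq_len(m)))))
    expect_equal(adj, direct)
    expect_true(all(diff(adj[o]) >= -1e-15))
  }
})

test_that("time-course contrasts cover every later time point", {
  cfg <- sim_config(seed = 5, n_genes = 120, noise_sd = 0,
                    effect_logfc = 1.5, frac_activated = 0.2,
                    frac_repressed = 0.2)
  sim <- simulate_timecourse(cfg)
  ctr <- timecourse_contrasts(sim$expression)
  expect_named(ctr, c("18", "36", "53", "72"))
  # noise-free logFC equals the planted trajectory exactly
  for (t in names(ctr)) {
    got <- setNames(ctr[[t]]$logFC, ctr[[t]]$gene)
    expect_equal(got[rownames(sim$truth$trajectory)],
                 sim$truth$trajectory[, t], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # two-time design gives one contrast; absent baseline errors
  cfg2 <- sim_config(seed = 5, n_genes = 30, time_points_h = c(0, 24))
  expect_length(timecourse_contrasts(simulate_timecourse(cfg2)$expression), 1)
  expect_error(timecourse_contrasts(sim$expression, baseline_time = 7),
               "baseline")
})

test_that("results are invariant under sample-column permutation", {
  cfg <- sim_config(seed = 19, n_genes = 80)
  em <- simulate_timecourse(cfg)$expression
  perm <- sample(ncol(em$values))
  em2 <- expression_matrix(em$values[, perm], em$samples[perm, ])
  r1 <- timecourse_contrasts(em)[["36"]]
  r2 <- timecourse_contrasts(em2)[["36"]]
  expect_equal(r1$t_mod, r2$t_mod, tolerance = 1e-12)
  expect_equal(r1$p_adj, r2$p_adj, tolerance = 1e-12)
})
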