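# End-to-end orchestration: simulate (optional) -> differential
# expression -> promoter motif counting -> binned motif correlation ->
# gene-set overlaps -> growth statistics, under one seeded
# configuration, writing every intermediate table plus a JSON report.

#' Configuration for a pipeline run
#'
#' Paths may point at existing input files; any path left \code{NULL}
#' with the \code{"simulate"} stage enabled is generated synthetically
#' into \code{out_dir} first.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Master seed; stage generators derive their own streams
#'   from it.
#' @param expression_matrix,sample_sheet,gene_models,tfbs_sites,growth_table
#'   Input paths, or \code{NULL} to use the simulated ones.
#' @param stages Character vector of stages to run, a subset of
#'   \code{c("simulate", "diffexpr", "motifcount", "correlate",
#'   "overlap", "growth")}.
#' @param n_bins logFC bins for the correlation statistic.
#' @param upstream_bp Promoter window length.
#' @param overlap_rule Site-membership rule for promoter counting.
#' @param p_kind Which p-value thresholds of gene-set rules refer to.
#' @param universe Optional universe size override is not supported; a
#'   character vector of gene ids to use as the overlap universe, or
#'   \code{NULL} for all genes of the headline contrast.
#' @param headline_time_h Time point (hours) whose contrast feeds the
#'   headline correlation and overlap stages (default 36).
#' @param up_rule,down_rule \code{\link{gene_set_rule}}s applied to the
#'   headline contrast to form the rising and falling gene sets.
#' @param n_permutations Label permutations for the growth test.
#' @param sim_cfg,promoter_cfg,growth_cfg Optional generator configs;
#'   defaults are derived from \code{seed}.
#' @return A list of class \code{"run_config"}.
#' @export
run_config <- function(out_dir,
                       seed = 1L,
                       expression_matrix = NULL,
                       sample_sheet = NULL,
                       gene_models = NULL,
                       tfbs_sites = NULL,
                       growth_table = NULL,
                       stages = c("simulate", "diffexpr", "motifcount",
                                  "correlate", "overlap", "growth"),
                       n_bins = 100L,
                       upstream_bp = 1000L,
                       overlap_rule = c("midpoint", "contained", "any"),
                       p_kind = c("adjusted", "raw"),
                       universe = NULL,
                       headline_time_h = 36,
                       up_rule = gene_set_rule("up", 1, 0.05,
                                               match.arg(p_kind)),
                       down_rule = gene_set_rule("down", 0.7, 0.05,
                                                 match.arg(p_kind)),
                       n_permutations = 999L,
                       sim_cfg = NULL,
                       promoter_cfg = NULL,
                       growth_cfg = NULL) {
  overlap_rule <- match.arg(overlap_rule)
  p_kind <- match.arg(p_kind)
  known <- c("simulate", "diffexpr", "motifcount", "correlate",
             "overlap", "growth")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  if (is.null(sim_cfg)) sim_cfg <- sim_config(seed = seed)
  if (is.null(promoter_cfg))
    promoter_cfg <- promoter_sim_config(seed = seed + 1L)
  if (is.null(growth_cfg)) growth_cfg <- growth_sim_config(seed = seed + 2L)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 paths = list(expression_matrix = expression_matrix,
                              sample_sheet = sample_sheet,
                              gene_models = gene_models,
                              tfbs_sites = tfbs_sites,
                              growth_table = growth_table),
                 stages = stages, n_bins = as.integer(n_bins),
                 upstream_bp = as.integer(upstream_bp),
                 overlap_rule = overlap_rule, p_kind = p_kind,
                 universe = universe, headline_time_h = headline_time_h,
                 up_rule = up_rule, down_rule = down_rule,
                 n_permutations = as.integer(n_permutations),
                 sim_cfg = sim_cfg, promoter_cfg = promoter_cfg,
                 growth_cfg = growth_cfg),
            class = "run_config")
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE))
}

require_path <- function(stage, path, what) {
  if (is.null(path) || !file.exists(path))
    stop("stage '", stage, "': missing ", what, " file: ",
         if (is.null(path)) "<not set>" else path, call. = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order, writes every
#' intermediate table into \code{config$out_dir}, and returns (and
#' writes as \code{report.json}) a machine-readable report with
#' per-stage row counts, the chosen parameters, the top motif
#' correlations per contrast, all overlap results, the growth-test
#' results, the seed, and an MD5 content hash of every input file.
#' Identical config and seed give an identical report.
#'
#' @param config A \code{\link{run_config}}.
#' @return The report, invisibly.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(config$out_dir, ...)
  paths <- config$paths
  on <- function(s) s %in% config$stages
  report <- list(seed = config$seed,
                 parameters = list(n_bins = config$n_bins,
                                   upstream_bp = config$upstream_bp,
                                   overlap_rule = config$overlap_rule,
                                   p_kind = config$p_kind,
                                   headline_time_h = config$headline_time_h,
                                   n_permutations = config$n_permutations),
                 stages = list(), warnings = list())

  if (on("simulate")) {
    stage_try("simulate", {
      sim <- simulate_timecourse(config$sim_cfg)
      land <- simulate_promoter_landscape(sim$truth, config$promoter_cfg)
      growth <- simulate_growth_curves(config$growth_cfg)
      if (is.null(paths$expression_matrix)) {
        paths$expression_matrix <- p("expression_matrix.tsv")
        paths$sample_sheet <- p("sample_sheet.tsv")
        write_expression_table(sim$expression, paths$expression_matrix,
                               paths$sample_sheet)
      }
      if (is.null(paths$gene_models)) {
        paths$gene_models <- p("gene_models.txt")
        write_gene_models(land$gene_models, paths$gene_models)
      }
      if (is.null(paths$tfbs_sites)) {
        paths$tfbs_sites <- p("tfbs_sites.txt")
        write_tfbs_sites(land$tfbs_sites, paths$tfbs_sites)
      }
      if (is.null(paths$growth_table)) {
        paths$growth_table <- p("growth_curves.tsv")
        write_growth_table(growth, paths$growth_table)
      }
      write_truth_json(land$truth, p("truth.json"))
      report$stages$simulate <- list(
        n_genes = nrow(sim$expression$values),
        n_samples = ncol(sim$expression$values),
        n_tfbs_records = nrow(land$tfbs_sites),
        n_animals = length(unique(growth$animal_id)))
    })
  }

  contrasts <- NULL
  if (on("diffexpr")) {
    stage_try("diffexpr", {
      em <- read_expression_table(
        require_path("diffexpr", paths$expression_matrix, "expression matrix"),
        require_path("diffexpr", paths$sample_sheet, "sample sheet"))
      em <- filter_low_expression(em)
      contrasts <- timecourse_contrasts(em)
      for (nm in names(contrasts))
        write_contrast_result(contrasts[[nm]],
                              p(sprintf("contrast_%sh.tsv", nm)))
      report$stages$diffexpr <- list(
        n_features_after_filter = nrow(em$values),
        contrasts = names(contrasts))
    })
  }

  counts <- NULL
  if (on("motifcount")) {
    stage_try("motifcount", {
      gm <- read_gene_models(
        require_path("motifcount", paths$gene_models, "gene model"))
      sites <- read_tfbs_sites(
        require_path("motifcount", paths$tfbs_sites, "TFBS"))
      windows <- promoter_windows(gm, upstream_bp = config$upstream_bp)
      counts <- count_motif_hits(windows, sites,
                                  rule = config$overlap_rule)
      write_promoter_bed(windows, p("promoter_windows.bed"))
      write_motif_counts(counts, p("motif_counts.tsv"))
      report$stages$motifcount <- list(n_genes = nrow(counts),
                                        n_motifs = ncol(counts),
                                        n_sites = nrow(sites))
    })
  }

  if (on("correlate")) {
    stage_try("correlate", {
      if (is.null(contrasts) || is.null(counts))
        stop("requires the diffexpr and motifcount stages")
      top <- list()
      for (nm in names(contrasts)) {
        mc <- correlate_motifs(counts, contrasts[[nm]],
                               n_bins = config$n_bins)
        ranked <- rank_motifs(mc)
        write_motif_correlations(ranked,
                                 p(sprintf("motif_correlation_%sh.tsv", nm)))
        top[[nm]] <- utils::head(ranked, 20)
      }
      report$stages$correlate <- list(n_contrasts = length(contrasts),
                                       top_motifs = top)
    })
  }

  if (on("overlap")) {
    stage_try("overlap", {
      if (is.null(contrasts))
        stop("requires the diffexpr stage")
      hl <- as.character(config$headline_time_h)
      if (!hl %in% names(contrasts))
        stop("headline time ", hl, " h has no contrast")
      headline <- contrasts[[hl]]
      universe <- if (is.null(config$universe)) headline$gene else
        config$universe
      sets <- list(
        define_gene_set(headline, config$up_rule,
                        sprintf("up_%sh", hl)),
        define_gene_set(headline, config$down_rule,
                        sprintf("down_%sh", hl)))
      # consistency set: rising genes at the final time point
      last <- names(contrasts)[length(contrasts)]
      if (last != hl)
        sets <- c(sets, list(define_gene_set(contrasts[[last]],
                                             config$up_rule,
                                             sprintf("up_%sh", last))))
      oa <- overlap_analysis(sets, universe)
      write_overlap_report(oa, p("overlap_report.tsv"))
      jsonlite::write_json(as.list(oa$venn), p("venn_regions.json"),
                           auto_unbox = TRUE)
      report$stages$overlap <- list(pairs = oa$pairs,
                                     venn = as.list(oa$venn),
                                     universe_size = oa$universe_size)
    })
  }

  if (on("growth")) {
    stage_try("growth", {
      gcs <- read_growth_table(
        require_path("growth", paths$growth_table, "growth table"))
      perm <- curve_permutation_test(gcs,
                                     n_permutations = config$n_permutations,
                                     seed = config$seed)
      daily <- per_day_rank_tests(gcs)
      growth_out <- list(observed_stat = perm$observed_stat,
                         p_value = perm$p_value,
                         n_permutations = perm$n_permutations,
                         seed = perm$seed, statistic = perm$statistic,
                         per_day = daily)
      jsonlite::write_json(growth_out, p("growth_stats.json"),
                           auto_unbox = TRUE, digits = NA)
      report$stages$growth <- growth_out
    })
  }

  report$input_md5 <- lapply(Filter(Negate(is.null), paths),
                             function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report)
}
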