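#' Pipeline configuration
#'
#' Every stage parameter of the end-to-end pipeline, with the defaults the
#' package uses throughout: QC gates 5 cells/gene, 200-7000 genes/cell, 20%
#' mitochondrial; 2000 HVGs; 20 PCs; canonical scorer defaults; IQR state
#' rule; DE at p < 0.01 and |log2FC| > 0.25; soft power 12, 25-cell
#' metacells, 25 hub genes per module. Unknown keys are rejected.
#'
#' @param qc,hvg,pca,scoring,de,modules,select,cohort Named lists of
#'   stage-parameter overrides.
#' @param fusion Consensus fusion rule (`"mean"` or `"median"`).
#' @param seed Integer seed driving every stochastic stage.
#' @return A `run_config` list.
#' @export
run_config <- function(qc = list(), hvg = list(), pca = list(),
                       scoring = list(), fusion = "mean", de = list(),
                       modules = list(), select = list(), cohort = list(),
                       seed = 1L) {
  defaults <- list(
    qc = list(min_cells_per_gene = 5L, min_genes_per_cell = 200L,
              max_genes_per_cell = 7000L, max_mito_fraction = 0.20,
              mito_prefix = "MT-"),
    hvg = list(n_hvgs = 2000L, n_bins = 20L),
    pca = list(n_pcs = 20L),
    scoring = list(auc_max_rank_fraction = 0.05, ucell_max_rank = 1500L,
                   ssgsea_alpha = 0.25, module_n_bins = 24L,
                   module_n_controls = 100L),
    fusion = "mean",
    de = list(p_max = 0.01, lfc_min = 0.25),
    modules = list(metacell_k = 25L, soft_power = 12L, min_module_size = 30L,
                   cut_height = 0.995, n_hub_genes = 25L, n_genes = 200L),
    select = list(max_candidates = 40L, lasso_n_repeats = 5L,
                  cox_p_max = 0.05, rf_n_top = 20L, rf_n_trees = 500L,
                  boruta_max_iter = 50L, boruta_n_trees = 150L,
                  xgb_n_rounds = 100L),
    cohort = list(n_samples = 500L, n_informative = 3L, effect_size = 1.5,
                  censoring_rate = 0.3),
    seed = 1L
  )
  supplied <- list(qc = qc, hvg = hvg, pca = pca, scoring = scoring,
                   de = de, modules = modules, select = select,
                   cohort = cohort)
  for (stage in names(supplied)) {
    unknown <- setdiff(names(supplied[[stage]]), names(defaults[[stage]]))
    if (length(unknown)) {
      stop(sprintf("unknown %s config key: '%s'", stage, unknown[1]))
    }
    defaults[[stage]] <- utils::modifyList(defaults[[stage]], supplied[[stage]])
  }
  defaults$fusion <- match.arg(fusion, c("mean", "median"))
  defaults$seed <- as.integer(seed)
  structure(defaults, class = "run_config")
}

#' Run the end-to-end lactylation-state pipeline
#'
#' QC, log-normalization, HVG selection, PCA, five-scorer consensus and IQR
#' state assignment, LHS-vs-LLS differential expression, metacell
#' co-expression modules, the DEG-module overlap, and the five-algorithm
#' feature-selection intersection on a cohort restricted to the candidate
#' genes. Every intermediate table is written as TSV into `dir`, plus a
#' JSON manifest with versions, the seed, every threshold used, and
#' per-stage row counts.
#'
#' @param counts A [count_matrix()] (counts layer).
#' @param signature Character vector of signature genes (or [read_gmt()]
#'   tibble; first set used).
#' @param dir Output directory.
#' @param config A [run_config()].
#' @param cohort Optional cohort tibble for the selection stage; when
#'   `NULL`, a cohort with planted informative genes is simulated over the
#'   candidate genes (the demo path).
#' @return Invisible list: `dir`, `panel`, `de`, `modules`,
#'   `module_assoc`, `candidates`, `selection`, `cohort_truth`, `manifest`.
#' @export
run_pipeline <- function(counts, signature, dir, config = run_config(),
                         cohort = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  if (is.data.frame(signature)) signature <- signature$genes[[1]]
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  log_msg <- function(fmt, ...) message(sprintf(paste0("[lactoscore] ", fmt), ...))
  manifest <- list(
    package = as.character(utils::packageVersion("lactoscore")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    params = unclass(config),
    stages = list()
  )
  add_stage <- function(name, rows) {
    manifest$stages[[name]] <<- rows
  }

  log_msg("QC: gates min_cells_per_gene=%d genes/cell=[%d,%d] mito<=%.2f",
          config$qc$min_cells_per_gene, config$qc$min_genes_per_cell,
          config$qc$max_genes_per_cell, config$qc$max_mito_fraction)
  qc <- apply_qc(counts, do.call(qc_thresholds, config$qc))
  write_report(qc$report, file.path(dir, "qc_report.tsv"))
  add_stage("qc_cells", nrow(qc$counts$values))
  ln <- lognormalize(qc$counts)

  log_msg("HVG: n_hvgs=%d n_bins=%d", config$hvg$n_hvgs, config$hvg$n_bins)
  hvgs <- select_hvgs(ln, config$hvg$n_hvgs, config$hvg$n_bins)
  write_report(tibble::tibble(gene = hvgs), file.path(dir, "hvgs.tsv"))
  add_stage("hvgs", length(hvgs))

  log_msg("PCA: n_pcs=%d", config$pca$n_pcs)
  emb <- run_pca(ln, hvgs, config$pca$n_pcs)

  log_msg("scoring: k_frac=%.3f r_max=%d alpha=%.2f bins=%d controls=%d fusion=%s",
          config$scoring$auc_max_rank_fraction, config$scoring$ucell_max_rank,
          config$scoring$ssgsea_alpha, config$scoring$module_n_bins,
          config$scoring$module_n_controls, config$fusion)
  sp <- do.call(scoring_params, c(config$scoring, list(seed = config$seed)))
  panel <- score_all(ln, signature, sp)
  panel <- classify_states(panel, config$fusion)
  write_report(panel, file.path(dir, "score_panel.tsv"))
  add_stage("scored_cells", nrow(panel))

  log_msg("DE LHS vs LLS: p_max=%.3g lfc_min=%.2f", config$de$p_max, config$de$lfc_min)
  states <- stats::setNames(panel$state, panel$cell)
  de <- de_states(ln, states, config$de$p_max, config$de$lfc_min)
  write_report(de, file.path(dir, "de_genes.tsv"))
  add_stage("de_genes", nrow(de))

  log_msg("modules: metacell_k=%d soft_power=%d min_size=%d cut=%.3f genes=%d",
          config$modules$metacell_k, config$modules$soft_power,
          config$modules$min_module_size, config$modules$cut_height,
          config$modules$n_genes)
  # network over the top HVGs plus the state-associated up-regulated genes,
  # so the lactylation program is represented in the module pool
  up_for_modules <- de$gene[de$direction == "up"]
  up_for_modules <- up_for_modules[seq_len(min(length(up_for_modules),
                                               config$modules$n_genes))]
  mod_genes <- union(hvgs[seq_len(min(config$modules$n_genes, length(hvgs)))],
                     up_for_modules)
  mc <- make_metacells(qc$counts, emb, config$modules$metacell_k)
  mc_expr <- mc$expression
  mc_expr <- count_matrix(mc_expr$values[, mod_genes, drop = FALSE],
                          layer = "lognorm")
  mods <- find_coexpression_modules(
    mc_expr,
    wgcna_params(config$modules$soft_power, config$modules$min_module_size,
                 config$modules$cut_height, config$modules$metacell_k,
                 config$modules$n_hub_genes)
  )
  write_report(tidy(mods), file.path(dir, "modules.tsv"))
  add_stage("module_genes", sum(mods$modules != "grey"))

  mc_state <- vapply(mc$members, function(ids) {
    names(which.max(table(states[ids])))
  }, character(1))
  assoc <- module_state_association(mods, mc_state)
  write_report(assoc, file.path(dir, "module_state_association.tsv"))

  up_genes <- de$gene[de$direction == "up"]
  module_members <- names(mods$modules)[mods$modules != "grey"]
  candidates <- intersect_genes(up_genes, module_members)
  if (length(candidates) > config$select$max_candidates) {
    candidates <- candidates[seq_len(config$select$max_candidates)]
  }
  write_report(tibble::tibble(gene = candidates),
               file.path(dir, "candidate_genes.tsv"))
  add_stage("candidates", length(candidates))
  log_msg("candidate pool (up-DEG within modules): %d genes", length(candidates))

  cohort_truth <- NULL
  if (is.null(cohort)) {
    if (length(candidates) < 5) {
      stop(sprintf("only %d candidate genes at the selection stage: too few for the five selectors (input %s)",
                   length(candidates), dir))
    }
    sim <- sim_config(
      cohort_spec = c(config$cohort, list(n_genes = length(candidates))),
      seed = config$seed
    )
    ch <- simulate_cohort(sim, gene_names = candidates)
    cohort <- ch$cohort
    cohort_truth <- ch$truth
  }
  log_msg("selection: %d candidates, cox p<%.2f, rf top %d, boruta alpha=0.01",
          length(candidates), config$select$cox_p_max, config$select$rf_n_top)
  sel <- select_features(
    cohort, intersect_genes(candidates, setdiff(names(cohort),
                                                c("sample_id", "label", "time", "event"))),
    seed = config$seed,
    lasso = list(n_repeats = config$select$lasso_n_repeats),
    unicox = list(p_max = config$select$cox_p_max),
    rf = list(n_top = config$select$rf_n_top, n_trees = config$select$rf_n_trees),
    boruta = list(max_iter = config$select$boruta_max_iter,
                  n_trees = config$select$boruta_n_trees),
    xgb = list(n_rounds = config$select$xgb_n_rounds)
  )
  write_report(tidy(sel), file.path(dir, "selection.tsv"))
  write_report(tibble::tibble(gene = sel$intersection),
               file.path(dir, "hub_genes.tsv"))
  add_stage("hub_genes", length(sel$intersection))

  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(
    dir = dir, panel = panel, de = de, modules = mods, module_assoc = assoc,
    candidates = candidates, selection = sel, cohort_truth = cohort_truth,
    manifest = manifest
  ))
}

#' One-command synthetic demo
#'
#' Simulates single-cell data with a planted lactylation-high subpopulation
#' (2000 cells, 3000 genes, 50-gene signature, fold 4, 25% planted) and
#' runs the full pipeline on it, including a simulated cohort over the
#' candidate genes for the selection stage.
#'
#' @param seed Integer seed.
#' @param dir Output directory (default: a fresh temporary directory).
#' @param config Optional [run_config()] override; its seed is replaced by
#'   `seed`.
#' @return The [run_pipeline()] result, plus `sc_truth` (the single-cell
#'   ground truth).
#' @export
run_demo <- function(seed = 1L, dir = tempfile("lactoscore_demo_"),
                     config = NULL) {
  if (is.null(config)) config <- run_config(seed = seed)
  config$seed <- as.integer(seed)
  sim <- simulate_sc_counts(sim_config(seed = seed))
  res <- run_pipeline(sim$counts, sim$truth$signature_genes, dir, config)
  res$sc_truth <- sim$truth
  invisible(res)
}
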