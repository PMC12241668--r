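#' Simulation configuration
#'
#' One configuration object drives all four generators. Counts are negative
#' binomial around log-normal gene baselines (the standard overdispersed
#' model for UMI data); a planted fraction of cells over-expresses a
#' designated "lactylation" signature by a configurable fold; a small block
#' of `MT-` prefixed genes carries a controlled share of each cell's counts.
#'
#' @param n_cells Number of cells (or spatial spots).
#' @param n_genes Number of genes.
#' @param n_celltypes Number of discrete cell types (each with its own
#'   marker-gene block, giving clusterable structure).
#' @param lactylation_set_size Size of the planted signature.
#' @param lhs_fraction Fraction of cells planted as signature-high, in (0,1).
#' @param lactylation_fold Mean multiplier on signature genes in planted
#'   cells; must be >= 1 (1 = null).
#' @param mito_fraction_range Length-2 range of per-cell mitochondrial count
#'   fractions.
#' @param nb_dispersion Negative-binomial dispersion phi (variance
#'   mu + phi mu^2); `rnbinom` size is `1/phi`.
#' @param module_spec List of `c(module_size, within_correlation)` pairs for
#'   [simulate_modular_expression()].
#' @param cohort_spec Named list for [simulate_cohort()]: `n_samples`,
#'   `n_genes`, `n_informative`, `effect_size` (log-odds and log-hazard per
#'   SD of expression), `censoring_rate`.
#' @param seed Integer seed; every generator is a pure function of the
#'   config including the seed. Each generator draws from its own stream so
#'   adding one does not perturb the others.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cells = 2000, n_genes = 3000, n_celltypes = 4,
                       lactylation_set_size = 50, lhs_fraction = 0.25,
                       lactylation_fold = 4,
                       mito_fraction_range = c(0.02, 0.10),
                       nb_dispersion = 0.5,
                       module_spec = list(c(50, 0.8), c(50, 0.8)),
                       cohort_spec = list(n_samples = 500, n_genes = 50,
                                          n_informative = 3,
                                          effect_size = 1.5,
                                          censoring_rate = 0.3),
                       seed = 1L) {
  cfg <- list(
    n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
    n_celltypes = as.integer(n_celltypes),
    lactylation_set_size = as.integer(lactylation_set_size),
    lhs_fraction = lhs_fraction, lactylation_fold = lactylation_fold,
    mito_fraction_range = mito_fraction_range,
    nb_dispersion = nb_dispersion, module_spec = module_spec,
    cohort_spec = utils::modifyList(
      list(n_samples = 500L, n_genes = 50L, n_informative = 3L,
           effect_size = 1.5, censoring_rate = 0.3),
      cohort_spec
    ),
    seed = as.integer(seed)
  )
  if (cfg$lactylation_set_size > cfg$n_genes) {
    stop("lactylation_set_size exceeds n_genes")
  }
  if (sum(vapply(cfg$module_spec, `[`, numeric(1), 1)) > cfg$n_genes) {
    stop("module sizes exceed n_genes")
  }
  if (cfg$lhs_fraction <= 0 || cfg$lhs_fraction >= 1) {
    stop("lhs_fraction must be in (0,1)")
  }
  if (cfg$lactylation_fold < 1) stop("lactylation_fold must be >= 1")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (length(cfg$mito_fraction_range) != 2 ||
      any(cfg$mito_fraction_range < 0) || any(cfg$mito_fraction_range >= 1) ||
      diff(cfg$mito_fraction_range) < 0) {
    stop("mito_fraction_range must be an increasing pair in [0,1)")
  }
  structure(cfg, class = "sim_config")
}

# independent seed stream per generator
.seed_stream <- function(config, stream) {
  offsets <- c(sc = 1L, modular = 2L, cohort = 3L, spatial = 4L)
  set.seed((config$seed %% 1000000L) * 1000L + offsets[[stream]])
}

#' Simulate single-cell counts with a planted lactylation-high subpopulation
#'
#' Negative-binomial counts around log-normal gene baselines, with discrete
#' cell types (marker-gene blocks), a planted subset of cells whose
#' signature-gene means are multiplied by `lactylation_fold`, and `MT-`
#' prefixed mitochondrial genes contributing a per-cell fraction drawn from
#' `mito_fraction_range`.
#'
#' @param config A [sim_config()].
#' @return A list with `counts` (a [count_matrix()]) and `truth` (list with
#'   `planted_high_cells`, `signature_genes`, `celltype`, `mito_genes`).
#' @export
simulate_sc_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .seed_stream(config, "sc")
  n <- config$n_cells
  g <- config$n_genes
  n_mito <- min(10L, max(2L, g %/% 100L))
  gene_names <- c(
    sprintf("MT-G%d", seq_len(n_mito)),
    sprintf("G%05d", seq_len(g - n_mito))
  )
  cell_names <- sprintf("cell%05d", seq_len(n))
  is_mito <- seq_len(g) <= n_mito

  base_mu <- stats::rlnorm(g, meanlog = 0, sdlog = 1)
  celltype <- sample(rep_len(seq_len(config$n_celltypes), n))
  # per-type marker blocks among non-mito, giving clusterable structure
  non_mito_idx <- which(!is_mito)
  # signatures are curated from expressed genes: plant on the upper half of
  # baseline abundance so the fold is observable over sampling noise
  expressed <- non_mito_idx[base_mu[non_mito_idx] >= stats::median(base_mu[non_mito_idx])]
  sig_idx <- sort(sample(expressed, config$lactylation_set_size))
  marker_pool <- setdiff(non_mito_idx, sig_idx)
  n_markers <- min(100L, length(marker_pool) %/% max(1L, config$n_celltypes))
  marker_idx <- split(
    sample(marker_pool, n_markers * config$n_celltypes),
    rep(seq_len(config$n_celltypes), each = n_markers)
  )
  planted <- sort(sample(seq_len(n), round(config$lhs_fraction * n)))

  mu <- matrix(rep(base_mu, each = n), nrow = n)
  for (t in seq_len(config$n_celltypes)) {
    mu[celltype == t, marker_idx[[t]]] <- mu[celltype == t, marker_idx[[t]]] * 3
  }
  mu[planted, sig_idx] <- mu[planted, sig_idx] * config$lactylation_fold

  # mitochondrial share: per-cell target fraction, split over MT genes
  f_c <- stats::runif(n, config$mito_fraction_range[1], config$mito_fraction_range[2])
  non_mito_total <- rowSums(mu[, !is_mito, drop = FALSE])
  mito_w <- stats::rlnorm(n_mito, 0, 0.5)
  mito_w <- mito_w / sum(mito_w)
  mu[, is_mito] <- outer(f_c / (1 - f_c) * non_mito_total, mito_w)

  counts <- matrix(
    stats::rnbinom(n * g, mu = as.vector(mu), size = 1 / config$nb_dispersion),
    nrow = n
  )
  dimnames(counts) <- list(cell_names, gene_names)
  list(
    counts = count_matrix(counts, layer = "counts"),
    truth = list(
      planted_high_cells = cell_names[planted],
      signature_genes = gene_names[sig_idx],
      celltype = stats::setNames(celltype, cell_names),
      mito_genes = gene_names[is_mito]
    )
  )
}

#' Simulate block-correlated expression for co-expression module recovery
#'
#' Each module draws a latent factor per sample; member genes are
#' `sqrt(rho) * factor + sqrt(1-rho) * noise`, so the expected within-module
#' Pearson correlation equals `rho` and between-module correlation is 0.
#' Remaining genes (up to `n_genes`) are pure noise. Values are shifted to
#' be non-negative (a global shift leaves every correlation unchanged) and
#' tagged as the normalized layer.
#'
#' @param config A [sim_config()]; `n_cells` is the sample count here and
#'   `module_spec` gives `c(size, within_correlation)` per module.
#' @return List with `expression` (a [count_matrix()], layer `"lognorm"`)
#'   and `truth$module_assignments` (named vector; 0 = noise gene).
#' @export
simulate_modular_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .seed_stream(config, "modular")
  n <- config$n_cells
  sizes <- vapply(config$module_spec, `[`, numeric(1), 1)
  rhos <- vapply(config$module_spec, `[`, numeric(1), 2)
  g <- config$n_genes
  if (sum(sizes) > g) stop("module sizes exceed n_genes")
  assignment <- rep(0L, g)
  x <- matrix(stats::rnorm(n * g), nrow = n)
  pos <- 1L
  for (m in seq_along(sizes)) {
    idx <- seq(pos, pos + sizes[m] - 1L)
    assignment[idx] <- m
    f <- stats::rnorm(n)
    x[, idx] <- sqrt(rhos[m]) * f + sqrt(1 - rhos[m]) * x[, idx]
    pos <- pos + sizes[m]
  }
  x <- x - min(x)
  gene_names <- sprintf("G%05d", seq_len(g))
  dimnames(x) <- list(sprintf("s%05d", seq_len(n)), gene_names)
  list(
    expression = count_matrix(x, layer = "lognorm"),
    truth = list(module_assignments = stats::setNames(assignment, gene_names))
  )
}

#' Simulate a labeled survival cohort with planted informative genes
#'
#' Per-sample expression is standard normal. A planted subset of genes
#' carries `effect_size` both as log-odds (binary label, logistic model) and
#' as log-hazard (exponential event times, proportional hazards). Censoring
#' is independent exponential, calibrated to the configured rate;
#' `censoring_rate = 0` means every event is observed.
#'
#' @param config A [sim_config()]; see `cohort_spec`.
#' @param gene_names Optional gene names (length `cohort_spec$n_genes`).
#' @return List with `cohort` (tibble: `sample_id`, `label`, `time`,
#'   `event`, then one column per gene) and
#'   `truth$informative_genes`.
#' @export
simulate_cohort <- function(config, gene_names = NULL) {
  stopifnot(inherits(config, "sim_config"))
  .seed_stream(config, "cohort")
  cs <- config$cohort_spec
  n <- cs$n_samples
  g <- cs$n_genes
  if (is.null(gene_names)) gene_names <- sprintf("G%05d", seq_len(g))
  stopifnot(length(gene_names) == g)
  x <- matrix(stats::rnorm(n * g), nrow = n, dimnames = list(NULL, gene_names))
  info <- sort(sample(seq_len(g), cs$n_informative))
  lp <- drop(x[, info, drop = FALSE] %*% rep(cs$effect_size, length(info)))
  label <- stats::rbinom(n, 1, stats::plogis(lp))
  lambda0 <- 0.1
  t_event <- stats::rexp(n, rate = lambda0 * exp(lp))
  if (cs$censoring_rate > 0) {
    r_c <- cs$censoring_rate / (1 - cs$censoring_rate) * lambda0 * mean(exp(lp))
    t_cens <- stats::rexp(n, rate = r_c)
  } else {
    t_cens <- rep(Inf, n)
  }
  cohort <- dplyr::bind_cols(
    tibble::tibble(
      sample_id = sprintf("sample%04d", seq_len(n)),
      label = label,
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens)
    ),
    tibble::as_tibble(x)
  )
  list(cohort = cohort,
       truth = list(informative_genes = gene_names[info]))
}

#' Simulate a spatial spot grid with a planted high-lactylation region
#'
#' Square grid of spots with negative-binomial counts; a contiguous central
#' block of spots (area about `lhs_fraction` of the grid) over-expresses the
#' signature genes by `lactylation_fold`.
#'
#' @param config A [sim_config()]; `n_cells` is the spot count.
#' @return List with `counts` (a [count_matrix()] of spots x genes),
#'   `coords` (tibble `spot`, `x`, `y`) and `truth` (`planted_region`,
#'   `signature_genes`).
#' @export
simulate_spatial <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .seed_stream(config, "spatial")
  side <- floor(sqrt(config$n_cells))
  n <- side * side
  g <- config$n_genes
  coords <- tidyr::expand_grid(x = seq_len(side), y = seq_len(side))
  coords <- tibble::tibble(spot = sprintf("spot%05d", seq_len(n)),
                           x = coords$x, y = coords$y)
  half <- floor(side * sqrt(config$lhs_fraction) / 2)
  mid <- (side + 1) / 2
  in_region <- abs(coords$x - mid) < half & abs(coords$y - mid) < half

  base_mu <- stats::rlnorm(g, 0, 1)
  sig_idx <- sort(sample(seq_len(g), config$lactylation_set_size))
  mu <- matrix(rep(base_mu, each = n), nrow = n)
  mu[in_region, sig_idx] <- mu[in_region, sig_idx] * config$lactylation_fold
  counts <- matrix(
    stats::rnbinom(n * g, mu = as.vector(mu), size = 1 / config$nb_dispersion),
    nrow = n,
    dimnames = list(coords$spot, sprintf("G%05d", seq_len(g)))
  )
  list(
    counts = count_matrix(counts, layer = "counts"),
    coords = coords,
    truth = list(planted_region = coords$spot[in_region],
                 signature_genes = colnames(counts)[sig_idx])
  )
}
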