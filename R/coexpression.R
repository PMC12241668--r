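#' Parameters for the co-expression module core
#'
#' @param soft_power Soft-threshold exponent beta for the adjacency
#'   (default 12). Set to `NULL` in [find_coexpression_modules()] to pick it
#'   from the scale-free fit.
#' @param min_module_size Smallest allowed module (default 30); smaller
#'   clusters fall into the unassigned `grey` pool.
#' @param cut_height Static tree-cut height as a fraction of the maximum
#'   merge height (default 0.995).
#' @param metacell_k Cells aggregated per metacell (default 25).
#' @param n_hub_genes Hub genes reported per module, ranked by kME
#'   (default 25).
#' @return A `wgcna_params` list.
#' @export
wgcna_params <- function(soft_power = 12L, min_module_size = 30L,
                         cut_height = 0.995, metacell_k = 25L,
                         n_hub_genes = 25L) {
  stopifnot(is.null(soft_power) || soft_power >= 1, min_module_size >= 3)
  structure(
    list(soft_power = soft_power, min_module_size = min_module_size,
         cut_height = cut_height, metacell_k = metacell_k,
         n_hub_genes = n_hub_genes),
    class = "wgcna_params"
  )
}

# WGCNA-style module label sequence, assigned by descending module size
.module_colors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "skyblue", "saddlebrown", "steelblue", "paleturquoise"
)

#' Aggregate cells into metacells
#'
#' De-sparsifies co-expression estimation by summing raw counts over each
#' seed cell and its `k - 1` nearest unused neighbors in the embedding
#' (Euclidean distance), greedily and without cell reuse, until fewer than
#' `k` unused cells remain. With n cells this yields `floor(n / k)`
#' metacells.
#'
#' @param x A [count_matrix()] (counts layer).
#' @param embedding Cells x dims matrix (e.g. from [run_pca()]), rows
#'   aligned with `x`.
#' @param k Cells per metacell (default 25); `k = 1` returns the input
#'   cells unchanged.
#' @return List with `expression` (log-normalized metacell
#'   [count_matrix()]), `counts` (raw aggregated counts) and `members`
#'   (list of member cell ids per metacell).
#' @export
make_metacells <- function(x, embedding, k = 25) {
  stopifnot(inherits(x, "count_matrix"), nrow(embedding) == nrow(x$values))
  m <- x$values
  n <- nrow(m)
  d <- as.matrix(stats::dist(embedding))
  unused <- rep(TRUE, n)
  members <- list()
  repeat {
    if (sum(unused) < k) break
    seed <- which(unused)[1]
    cand <- which(unused)
    sel <- cand[order(d[seed, cand])][seq_len(k)]
    members[[length(members) + 1]] <- rownames(m)[sel]
    unused[sel] <- FALSE
  }
  if (length(members) == 0) stop("fewer cells than k: no metacell can be formed")
  agg <- t(vapply(
    members,
    function(ids) Matrix::colSums(m[ids, , drop = FALSE]),
    numeric(ncol(m))
  ))
  rownames(agg) <- sprintf("metacell%04d", seq_along(members))
  colnames(agg) <- colnames(m)
  counts <- count_matrix(agg, layer = "counts")
  list(expression = lognormalize(counts), counts = counts, members = members)
}

.expr_matrix <- function(x) {
  if (inherits(x, "count_matrix")) as.matrix(.ensure_lognorm(x)$values) else as.matrix(x)
}

#' Pick the soft-threshold power from the scale-free fit
#'
#' For each candidate power, the adjacency is `|cor|^beta`; connectivity
#' `k_i` is its row sum. The scale-free fit R^2 regresses `log10 p(k)` on
#' `log10 k` over 10 connectivity bins and is sign-corrected (a positive
#' slope counts against the fit). The chosen power is the smallest with
#' R^2 at or above `rsq_cut`, else the argmax.
#'
#' @param x Expression ([count_matrix()] or samples x genes matrix).
#' @param powers Candidate powers (default 1:20).
#' @param rsq_cut Fit threshold (default 0.8).
#' @return List with `power` and `fit` (tibble: `power`, `r_squared`,
#'   `slope`, `mean_k`).
#' @export
pick_soft_power <- function(x, powers = 1:20, rsq_cut = 0.8) {
  m <- .expr_matrix(x)
  cm <- abs(stats::cor(m))
  diag(cm) <- 0
  rows <- purrr::map(powers, function(beta) {
    a <- cm^beta
    k <- colSums(a)
    fit <- .scale_free_fit(k)
    tibble::tibble(power = beta, r_squared = fit$r2, slope = fit$slope,
                   mean_k = mean(k))
  })
  fit <- dplyr::bind_rows(rows)
  ok <- which(fit$r_squared >= rsq_cut)
  if (length(ok)) {
    power <- fit$power[ok[1]]
  } else {
    power <- fit$power[which.max(fit$r_squared)]
    if (all(!is.finite(fit$r_squared)) || max(fit$r_squared, na.rm = TRUE) <= 0) {
      warning("degenerate connectivity distribution: falling back to argmax R^2")
    }
  }
  list(power = power, fit = fit)
}

.scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 2) return(list(r2 = -Inf, slope = NA_real_))
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks, include.lowest = TRUE)
  p_k <- tapply(k, bin, length) / length(k)
  k_mid <- tapply(k, bin, mean)
  keep <- !is.na(p_k) & p_k > 0 & k_mid > 0
  if (sum(keep) < 3) return(list(r2 = -Inf, slope = NA_real_))
  lx <- log10(k_mid[keep]); ly <- log10(p_k[keep])
  fit <- stats::lm(ly ~ lx)
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[2]
  list(r2 = if (slope < 0) r2 else -r2, slope = unname(slope))
}

#' Soft-threshold adjacency and topological overlap dissimilarity
#'
#' Adjacency `a_ij = |pearson(x_i, x_j)|^beta` (zero diagonal); the
#' topological overlap `TOM_ij = (sum_u a_iu a_uj + a_ij) /
#' (min(k_i, k_j) + 1 - a_ij)` rewards genes that share neighbors beyond
#' their direct connection. Returned as the dissimilarity `1 - TOM`
#' (symmetric, zero diagonal).
#'
#' @param x Expression ([count_matrix()] or samples x genes matrix).
#' @param beta Soft-threshold power.
#' @return List with `adjacency`, `tom` and `dissimilarity` matrices.
#' @export
adjacency_tom <- function(x, beta = 12) {
  m <- .expr_matrix(x)
  a <- abs(stats::cor(m))^beta
  diag(a) <- 0
  l <- a %*% a
  k <- colSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  diss <- 1 - tom
  diag(diss) <- 0
  list(adjacency = a, tom = tom, dissimilarity = diss)
}

#' Cut the gene tree into modules
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity, cut
#' statically at `cut_height` times the maximum merge height; clusters
#' smaller than `min_module_size` are pooled as `grey`. Module labels follow
#' the WGCNA color sequence in order of descending size.
#'
#' @param dissimilarity Symmetric dissimilarity matrix (from
#'   [adjacency_tom()]).
#' @param min_module_size Smallest retained module (default 30).
#' @param cut_height Fraction of the maximum merge height (default 0.995).
#' @return Named character vector: gene -> module label (`grey` =
#'   unassigned).
#' @export
cut_modules <- function(dissimilarity, min_module_size = 30, cut_height = 0.995) {
  tree <- stats::hclust(stats::as.dist(dissimilarity), method = "average")
  h <- cut_height * max(tree$height)
  cl <- stats::cutree(tree, h = h)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- rep("grey", length(cl))
  if (length(keep)) {
    ord <- keep[order(sizes[keep], decreasing = TRUE)]
    for (i in seq_along(ord)) {
      labels[cl == as.integer(ord[i])] <-
        .module_colors[(i - 1) %% length(.module_colors) + 1]
    }
  }
  stats::setNames(labels, colnames(dissimilarity))
}

#' Module eigengenes, kME and hub genes
#'
#' Each module's eigengene is the first principal component of its
#' standardized member expression, sign-fixed to correlate positively with
#' the module's mean expression. kME is the signed Pearson correlation of
#' every gene with every module eigengene; hub genes are the top module
#' members by own-module kME.
#'
#' @param x Expression ([count_matrix()] or samples x genes matrix).
#' @param modules Named gene -> module vector from [cut_modules()].
#' @param n_hub_genes Hub genes per module (default 25).
#' @return A `coexpression_modules` object: list with `modules`,
#'   `eigengenes` (samples x modules), `kme` (genes x modules), `hubs`
#'   (list), `n_hub_genes`.
#' @export
eigengene_kme <- function(x, modules, n_hub_genes = 25) {
  m <- .expr_matrix(x)
  modules <- modules[colnames(m)]
  mod_names <- setdiff(unique(modules), "grey")
  mod_names <- mod_names[order(match(mod_names, .module_colors))]
  if (length(mod_names) == 0) stop("no module to summarize (all genes grey)")
  eig <- vapply(mod_names, function(mod) {
    sub <- m[, modules == mod, drop = FALSE]
    sub <- scale(sub)
    sub[is.na(sub)] <- 0
    e <- stats::prcomp(sub, center = FALSE, scale. = FALSE, rank. = 1)$x[, 1]
    if (stats::cor(e, rowMeans(sub)) < 0) e <- -e
    e
  }, numeric(nrow(m)))
  rownames(eig) <- rownames(m)
  kme <- suppressWarnings(stats::cor(m, eig))
  kme[is.na(kme)] <- 0
  hubs <- lapply(mod_names, function(mod) {
    members <- names(modules)[modules == mod]
    members[order(kme[members, mod], decreasing = TRUE)][
      seq_len(min(n_hub_genes, length(members)))
    ]
  })
  names(hubs) <- mod_names
  structure(
    list(modules = modules, eigengenes = eig, kme = kme, hubs = hubs,
         n_hub_genes = n_hub_genes),
    class = "coexpression_modules"
  )
}

#' @export
print.coexpression_modules <- function(x, ...) {
  sizes <- table(x$modules)
  cat(sprintf("<coexpression_modules> %d modules over %d genes (%d grey)\n",
              ncol(x$eigengenes), length(x$modules),
              sum(x$modules == "grey")))
  print(sizes)
  invisible(x)
}

#' One-call module detection
#'
#' Chains [pick_soft_power()] (unless a power is given), [adjacency_tom()],
#' [cut_modules()] and [eigengene_kme()].
#'
#' @param x Expression ([count_matrix()] or samples x genes matrix),
#'   typically metacell expression from [make_metacells()].
#' @param params A [wgcna_params()].
#' @return A `coexpression_modules` object (with the power used in
#'   `$soft_power` and the fit table in `$power_fit` when it was searched).
#' @export
find_coexpression_modules <- function(x, params = wgcna_params()) {
  power <- params$soft_power
  fit <- NULL
  if (is.null(power)) {
    sp <- pick_soft_power(x)
    power <- sp$power
    fit <- sp$fit
  }
  net <- adjacency_tom(x, power)
  modules <- cut_modules(net$dissimilarity, params$min_module_size,
                         params$cut_height)
  res <- eigengene_kme(x, modules, params$n_hub_genes)
  res$soft_power <- power
  res$power_fit <- fit
  res
}

#' Associate module eigengenes with lactylation states
#'
#' Per module: the mean eigengene within each state plus a Kruskal-Wallis
#' test of the eigengene across the three states, BH-adjusted over modules.
#'
#' @param modules A `coexpression_modules` object (or a samples x modules
#'   eigengene matrix).
#' @param states State vector aligned with the eigengene rows.
#' @return Tibble: `module`, `mean_LLS`, `mean_LDTS`, `mean_LHS`, `p`,
#'   `p_adj`.
#' @export
module_state_association <- function(modules, states) {
  eig <- if (inherits(modules, "coexpression_modules")) modules$eigengenes else as.matrix(modules)
  states <- factor(states, levels = c("LLS", "LDTS", "LHS"))
  stopifnot(length(states) == nrow(eig))
  rows <- purrr::map(colnames(eig), function(mod) {
    e <- eig[, mod]
    means <- tapply(e, states, mean)
    p <- tryCatch(stats::kruskal.test(e, states)$p.value,
                  error = function(err) NA_real_)
    tibble::tibble(module = mod, mean_LLS = means[["LLS"]],
                   mean_LDTS = means[["LDTS"]], mean_LHS = means[["LHS"]],
                   p = p)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- stats::p.adjust(out$p, "BH")
  out
}
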