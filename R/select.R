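.cohort_parts <- function(cohort, genes = NULL) {
  meta <- c("sample_id", "label", "time", "event")
  if (is.null(genes)) genes <- setdiff(names(cohort), meta)
  missing <- setdiff(genes, names(cohort))
  if (length(missing)) stop(sprintf("gene '%s' not in cohort table", missing[1]))
  x <- as.matrix(cohort[genes])
  storage.mode(x) <- "double"
  list(x = x, genes = genes,
       label = cohort$label, time = cohort$time, event = cohort$event)
}

#' LASSO (L1 logistic) gene selection
#'
#' L1-penalized logistic regression of the binary label on standardized
#' expression. The penalty is chosen at the minimum cross-validated deviance
#' ("minimum criterion"), stabilized by repeating the cross-validation and
#' geometric-averaging the per-repeat lambda; selected genes are those with
#' a nonzero coefficient at that lambda.
#'
#' @param cohort Cohort tibble (`sample_id`, `label`, `time`, `event`, gene
#'   columns), e.g. from [simulate_cohort()].
#' @param genes Candidate genes (default: every gene column).
#' @param n_folds CV folds (default 10).
#' @param n_repeats CV repeats averaged into the final lambda (default 10).
#' @param seed Seed for fold assignment.
#' @return List with `algorithm`, `selected`, `lambda`, and `diagnostics`
#'   (tibble `gene`, `coefficient`).
#' @export
select_lasso <- function(cohort, genes = NULL, n_folds = 10, n_repeats = 10,
                         seed = 1L) {
  parts <- .cohort_parts(cohort, genes)
  y <- parts$label
  if (length(unique(y)) < 2) stop("label has a single class")
  x <- scale(parts$x)
  set.seed(seed)
  lambdas <- vapply(seq_len(n_repeats), function(i) {
    foldid <- sample(rep_len(seq_len(n_folds), nrow(x)))
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", foldid = foldid,
                            standardize = FALSE)
    cv$lambda.min
  }, numeric(1))
  lambda <- exp(mean(log(lambdas)))
  fit <- glmnet::glmnet(x, y, family = "binomial", standardize = FALSE)
  coefs <- as.matrix(stats::coef(fit, s = lambda))[-1, 1]
  list(
    algorithm = "lasso",
    selected = parts$genes[coefs != 0],
    lambda = lambda,
    diagnostics = tibble::tibble(gene = parts$genes, coefficient = unname(coefs))
  )
}

# Single-covariate Cox partial likelihood, Breslow tie handling,
# Newton-Raphson to |gradient| < tol.
.cox_fit_single <- function(x, time, event, tol = 1e-8, max_iter = 30) {
  ord <- order(time)
  x <- x[ord]; time <- time[ord]; event <- event[ord]
  n <- length(x)
  event_times <- unique(time[event == 1])
  deriv <- function(beta) {
    w <- exp(x * beta)
    # risk-set sums via reverse cumulative sums over sorted times
    rs0 <- rev(cumsum(rev(w)))
    rs1 <- rev(cumsum(rev(w * x)))
    rs2 <- rev(cumsum(rev(w * x^2)))
    first_at <- match(event_times, time)  # first index with this time
    d <- as.vector(table(factor(time[event == 1], levels = event_times)))
    s0 <- rs0[first_at]; s1 <- rs1[first_at]; s2 <- rs2[first_at]
    ll <- sum(x[event == 1] * beta) - sum(d * log(s0))
    grad <- sum(x[event == 1]) - sum(d * s1 / s0)
    info <- sum(d * (s2 / s0 - (s1 / s0)^2))
    list(ll = ll, grad = grad, info = info)
  }
  beta <- 0
  st <- deriv(beta)
  for (i in seq_len(max_iter)) {
    if (abs(st$grad) < tol) break
    if (st$info <= 0) return(list(converged = FALSE))
    step <- st$grad / st$info
    new_beta <- beta + step
    new_st <- deriv(new_beta)
    halvings <- 0
    while (new_st$ll < st$ll && halvings < 20) {
      step <- step / 2
      new_beta <- beta + step
      new_st <- deriv(new_beta)
      halvings <- halvings + 1
    }
    beta <- new_beta; st <- new_st
  }
  if (abs(st$grad) >= tol || st$info <= 0) return(list(converged = FALSE))
  se <- 1 / sqrt(st$info)
  list(converged = TRUE, beta = beta, se = se,
       p = 2 * stats::pnorm(-abs(beta / se)), loglik = st$ll)
}

#' Univariate Cox proportional-hazards gene selection
#'
#' One Cox model per gene: partial likelihood with Breslow tie handling and
#' a single standardized covariate, solved by Newton-Raphson; genes with a
#' Wald p-value below `p_max` are selected. Genes whose fit does not
#' converge are skipped with a warning.
#'
#' @inheritParams select_lasso
#' @param p_max Wald p-value cut (default 0.05).
#' @return List with `algorithm`, `selected`, and `diagnostics` (tibble
#'   `gene`, `log_hr`, `hr`, `se`, `p`).
#' @export
select_unicox <- function(cohort, genes = NULL, p_max = 0.05) {
  parts <- .cohort_parts(cohort, genes)
  if (sum(parts$event) == 0) stop("no events observed: Cox model is undefined")
  rows <- purrr::map(seq_along(parts$genes), function(j) {
    z <- as.vector(scale(parts$x[, j]))
    fit <- .cox_fit_single(z, parts$time, parts$event)
    if (!isTRUE(fit$converged)) {
      warning(sprintf("Cox fit did not converge for gene %s; skipped",
                      parts$genes[j]))
      return(NULL)
    }
    tibble::tibble(gene = parts$genes[j], log_hr = fit$beta,
                   hr = exp(fit$beta), se = fit$se, p = fit$p)
  })
  diag_tbl <- dplyr::bind_rows(rows)
  list(
    algorithm = "unicox",
    selected = diag_tbl$gene[diag_tbl$p < p_max],
    diagnostics = diag_tbl
  )
}

#' Random-forest gene selection
#'
#' Random-forest classifier on the binary label; genes are ranked by
#' out-of-bag permutation importance (mean decrease in accuracy, unscaled)
#' and the top `n_top` are selected.
#'
#' @inheritParams select_lasso
#' @param n_top Genes selected (default 20).
#' @param n_trees Trees (default 500).
#' @return List with `algorithm`, `selected`, and `diagnostics` (tibble
#'   `gene`, `importance`).
#' @export
select_rf <- function(cohort, genes = NULL, n_top = 20, n_trees = 500,
                      seed = 1L) {
  parts <- .cohort_parts(cohort, genes)
  if (length(unique(parts$label)) < 2) stop("label has a single class")
  set.seed(seed)
  fit <- randomForest::randomForest(parts$x, factor(parts$label),
                                    ntree = n_trees, importance = TRUE)
  imp <- randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
  ord <- order(imp, decreasing = TRUE)
  n_top <- min(n_top, length(parts$genes))
  list(
    algorithm = "rf",
    selected = parts$genes[ord[seq_len(n_top)]],
    diagnostics = tibble::tibble(gene = parts$genes, importance = unname(imp)) |>
      dplyr::arrange(dplyr::desc(.data$importance))
  )
}

#' Boruta all-relevant gene selection (shadow features)
#'
#' Each iteration appends a shuffled "shadow" copy of every gene, fits a
#' random forest on the augmented matrix, and records a hit for every real
#' gene whose permutation importance exceeds the best shadow importance.
#' Once enough iterations accumulate, a two-sided binomial test of the hit
#' count against 0.5 (Bonferroni-corrected across still-undecided genes)
#' confirms or rejects genes; the loop runs until all genes are decided or
#' `max_iter` is reached, and undecided genes are reported tentative.
#'
#' @inheritParams select_lasso
#' @param max_iter Maximum iterations (default 100; fewer than 10 is an
#'   error — the binomial test would be powerless).
#' @param alpha Decision level (default 0.01).
#' @param n_trees Trees per iteration forest (default 300).
#' @param min_iter Iterations before testing begins (default 5).
#' @return List with `algorithm`, `selected` (confirmed genes), and
#'   `diagnostics` (tibble `gene`, `decision`, `hits`, `iters`).
#' @export
select_boruta <- function(cohort, genes = NULL, max_iter = 100, alpha = 0.01,
                          seed = 1L, n_trees = 300, min_iter = 5) {
  if (max_iter < 10) stop("max_iter must be at least 10")
  parts <- .cohort_parts(cohort, genes)
  if (length(unique(parts$label)) < 2) stop("label has a single class")
  x <- parts$x
  p <- ncol(x)
  y <- factor(parts$label)
  set.seed(seed)
  hits <- stats::setNames(integer(p), parts$genes)
  iters <- stats::setNames(integer(p), parts$genes)
  decision <- stats::setNames(rep("tentative", p), parts$genes)
  for (it in seq_len(max_iter)) {
    undecided <- decision == "tentative"
    if (!any(undecided)) break
    shadow <- apply(x, 2, sample)
    colnames(shadow) <- paste0("shadow_", parts$genes)
    aug <- cbind(x, shadow)
    fit <- randomForest::randomForest(aug, y, ntree = n_trees,
                                      importance = TRUE)
    imp <- randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
    shadow_max <- max(imp[(p + 1):(2 * p)])
    hit <- imp[seq_len(p)] > shadow_max
    hits[undecided] <- hits[undecided] + hit[undecided]
    iters[undecided] <- iters[undecided] + 1L
    if (it >= min_iter) {
      n_und <- sum(undecided)
      for (g in names(which(undecided))) {
        p_hi <- stats::pbinom(hits[g] - 1, iters[g], 0.5, lower.tail = FALSE)
        p_lo <- stats::pbinom(hits[g], iters[g], 0.5)
        p_two <- min(1, 2 * min(p_hi, p_lo)) * n_und  # Bonferroni
        if (p_two < alpha) {
          decision[g] <- if (p_hi < p_lo) "confirmed" else "rejected"
        }
      }
    }
  }
  list(
    algorithm = "boruta",
    selected = names(decision)[decision == "confirmed"],
    diagnostics = tibble::tibble(gene = parts$genes,
                                 decision = unname(decision),
                                 hits = unname(hits), iters = unname(iters))
  )
}

#' Gradient-boosting gene selection
#'
#' Gradient-boosted trees on the binary label; genes are ranked by total
#' split gain. Selection keeps genes whose gain exceeds the mean gain over
#' all candidates (default) or the top `n_top`.
#'
#' @inheritParams select_lasso
#' @param rule `"mean_gain"` (default) or `"top_k"`.
#' @param n_top Genes kept under the `top_k` rule (default 9).
#' @param n_rounds Boosting rounds (default 200).
#' @param max_depth,eta Tree depth and learning rate.
#' @return List with `algorithm`, `selected`, and `diagnostics` (tibble
#'   `gene`, `gain`).
#' @export
select_xgb <- function(cohort, genes = NULL, rule = c("mean_gain", "top_k"),
                       n_top = 9, n_rounds = 200, seed = 1L,
                       max_depth = 3, eta = 0.3) {
  rule <- match.arg(rule)
  parts <- .cohort_parts(cohort, genes)
  if (length(unique(parts$label)) < 2) stop("label has a single class")
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(parts$x, label = parts$label)
  fit <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, nthread = 1, seed = seed),
    data = dtrain, nrounds = n_rounds, verbose = 0
  )
  imp <- xgboost::xgb.importance(model = fit)
  gain <- stats::setNames(rep(0, length(parts$genes)), parts$genes)
  gain[imp$Feature] <- imp$Gain
  selected <- if (rule == "mean_gain") {
    names(gain)[gain > mean(gain)]
  } else {
    names(sort(gain, decreasing = TRUE))[seq_len(min(n_top, length(gain)))]
  }
  list(
    algorithm = "xgb",
    selected = selected,
    diagnostics = tibble::tibble(gene = names(gain), gain = unname(gain)) |>
      dplyr::arrange(dplyr::desc(.data$gain))
  )
}

#' Run all five selectors and intersect their gene lists
#'
#' LASSO, univariate Cox, random forest, Boruta and gradient boosting on
#' the same cohort (Cox on the survival outcome, the rest on the binary
#' label), plus the strict five-way intersection.
#'
#' @inheritParams select_lasso
#' @param seed Seed forwarded to every stochastic selector.
#' @param lasso,unicox,rf,boruta,xgb Named lists of extra arguments for the
#'   individual selectors.
#' @return A `selection_report`: list with `selections` (named list of gene
#'   vectors), `diagnostics` (named list of tibbles), `intersection`, and
#'   `pairwise` (tibble of pairwise intersection sizes).
#' @export
select_features <- function(cohort, genes = NULL, seed = 1L,
                            lasso = list(), unicox = list(), rf = list(),
                            boruta = list(), xgb = list()) {
  runs <- list(
    lasso = do.call(select_lasso, c(list(cohort, genes, seed = seed), lasso)),
    unicox = do.call(select_unicox, c(list(cohort, genes), unicox)),
    rf = do.call(select_rf, c(list(cohort, genes, seed = seed), rf)),
    boruta = do.call(select_boruta, c(list(cohort, genes, seed = seed), boruta)),
    xgb = do.call(select_xgb, c(list(cohort, genes, seed = seed), xgb))
  )
  selections <- purrr::map(runs, "selected")
  report <- structure(
    list(selections = selections,
         diagnostics = purrr::map(runs, "diagnostics"),
         intersection = intersect_selections(selections),
         pairwise = .pairwise_intersections(selections)),
    class = "selection_report"
  )
  report
}

#' Strict intersection of per-algorithm gene lists
#'
#' @param selections A named list of character vectors (or a
#'   `selection_report`).
#' @return Character vector: genes selected by every algorithm.
#' @export
intersect_selections <- function(selections) {
  if (inherits(selections, "selection_report")) selections <- selections$selections
  Reduce(intersect_genes, selections)
}

.pairwise_intersections <- function(selections) {
  nm <- names(selections)
  pairs <- utils::combn(nm, 2, simplify = FALSE)
  dplyr::bind_rows(purrr::map(pairs, function(pr) {
    tibble::tibble(
      a = pr[1], b = pr[2],
      n_shared = length(intersect_genes(selections[[pr[1]]], selections[[pr[2]]]))
    )
  }))
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>\n")
  for (nm in names(x$selections)) {
    cat(sprintf("  %-7s %3d genes\n", nm, length(x$selections[[nm]])))
  }
  cat(sprintf("  five-way intersection: %s\n",
              if (length(x$intersection)) paste(x$intersection, collapse = ", ")
              else "(empty)"))
  invisible(x)
}
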