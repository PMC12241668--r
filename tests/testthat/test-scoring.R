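test_that("worked micro-examples reproduce their oracle values", {
  r <- setNames(1:10, paste0("g", 1:10))
  expect_equal(score_aucell(r, c("g1", "g2"), 0.5), 1.0)
  expect_equal(score_aucell(r, c("g3", "g6"), 0.5), 1 / 3, tolerance = 1e-12)
  expect_equal(score_aucell(r, c("g9", "g10"), 0.5), 0.0)
  expect_equal(score_ucell(r, c("g1", "g2"), 5), 1.0)
  expect_equal(score_ucell(r, c("g3", "g6"), 5), 0.4, tolerance = 1e-12)
  # both set genes beyond r_max: closed-form floor value
  ns <- 2; rmax <- 5
  floor_val <- 1 - (ns * (rmax + 1) - ns * (ns + 1) / 2) / (ns * rmax)
  expect_equal(score_ucell(r, c("g9", "g10"), 5), max(0, floor_val))
  expect_equal(score_singscore(r, c("g1", "g2")), 1.0)
  expect_equal(score_singscore(r, c("g9", "g10")), 0.0)
  # ascending ranks {8,5} = descending ranks {3,6}
  expect_equal(score_singscore(r, c("g3", "g6")), 0.625, tolerance = 1e-12)
})

test_that("every rank scorer matches brute force on all C(8,2) placements", {
  n <- 8
  placements <- combn(n, 2, simplify = FALSE)
  for (pl in placements) {
    cw <- cell_with_set_ranks(pl, n)
    r <- rank(-cw$expr)
    expect_equal(score_aucell(r, cw$set, 0.5),
                 oracle_aucell(pl, n, k = 4), tolerance = 1e-9)
    expect_equal(score_ucell(r, cw$set, 6),
                 oracle_ucell(pl, 6), tolerance = 1e-9)
    expect_equal(score_singscore(r, cw$set),
                 oracle_singscore(pl, n), tolerance = 1e-9)
    expect_equal(score_ssgsea(r, cw$set, 0.25),
                 oracle_ssgsea(pl, n, 0.25), tolerance = 1e-9)
  }
})

test_that("running-sum score walks a 5-gene toy step by step", {
  cw <- cell_with_set_ranks(c(1, 3), 5)
  r <- rank(-cw$expr)
  expect_equal(score_ssgsea(r, cw$set, 0.25),
               oracle_ssgsea(c(1, 3), 5, 0.25), tolerance = 1e-9)
  # promoting a set gene strictly increases the score (all placements, N=8)
  es <- vapply(combn(8, 2, simplify = FALSE), function(pl) {
    oracle_ssgsea(pl, 8, 0.25)
  }, numeric(1))
  # order placements by total rank: moving any member up increases ES
  for (fixed in 2:8) {
    others <- setdiff(seq_len(8), fixed)
    scores <- vapply(others, function(pos) {
      oracle_ssgsea(sort(c(fixed, pos)), 8, 0.25)
    }, numeric(1))
    expect_true(all(diff(scores[order(others)]) < 0))
  }
})

test_that("rank scorers are invariant under strictly monotone transforms", {
  set.seed(61)
  m <- matrix(rexp(20 * 50), 20, 50,
              dimnames = list(paste0("c", 1:20), paste0("g", 1:50)))
  set <- paste0("g", c(3, 11, 40))
  r1 <- rank_matrix(m)
  r2 <- rank_matrix(sqrt(m) * 10 + 1)
  expect_identical(r1, r2)
  for (fn in list(score_aucell, score_ucell, score_singscore,
                  function(r, s) score_ssgsea(r, s, 0.25))) {
    expect_equal(fn(r1, set), fn(r2, set))
  }
})

test_that("spiking the signature to the top makes that cell the argmax everywhere", {
  set.seed(62)
  m <- matrix(rpois(30 * 40, 5) + 0.0, 30, 40,
              dimnames = list(paste0("c", 1:30), paste0("g", 1:40)))
  set <- paste0("g", 1:4)
  m[17, set] <- 1000 + 1:4
  r <- rank_matrix(m)
  expect_equal(which.max(score_aucell(r, set)), 17L)
  expect_equal(which.max(score_ucell(r, set, 20)), 17L)
  expect_equal(which.max(score_singscore(r, set)), 17L)
  expect_equal(which.max(score_ssgsea(r, set)), 17L)
})

test_that("bounded scorers stay in [0,1] under ties and extremes", {
  set.seed(63)
  m <- matrix(rpois(50 * 30, 1) + 0.0, 50, 30,
              dimnames = list(paste0("c", 1:50), paste0("g", 1:30)))
  r <- rank_matrix(m)
  set <- paste0("g", c(1, 9, 22))
  for (s in list(score_aucell(r, set), score_ucell(r, set, 10),
                 score_singscore(r, set))) {
    expect_true(all(s >= 0 & s <= 1))
  }
  # ranks with ties are still a permutation-with-ties summing to N(N+1)/2
  expect_equal(unname(rowSums(r)), rep(30 * 31 / 2, 50))
})

test_that("module score is zero on flat expression and reproducible by seed", {
  m <- matrix(3, 10, 40,
              dimnames = list(paste0("c", 1:10), paste0("g", 1:40)))
  cm <- count_matrix(m, layer = "lognorm")
  s <- score_modulescore(cm, paste0("g", 1:5), seed = 1)
  expect_equal(unname(s), rep(0, 10))
  sim <- simulate_sc_counts(sim_config(n_cells = 100, n_genes = 300, seed = 15))
  ln <- lognormalize(sim$counts)
  a <- score_modulescore(ln, sim$truth$signature_genes, seed = 7)
  b <- score_modulescore(ln, sim$truth$signature_genes, seed = 7)
  expect_identical(a, b)
})

test_that("planted-high cells get higher module scores (rank test)", {
  sim <- simulate_sc_counts(sim_config(n_cells = 500, n_genes = 800,
                                       lactylation_set_size = 30,
                                       lactylation_fold = 4, seed = 16))
  ln <- lognormalize(sim$counts)
  s <- score_modulescore(ln, sim$truth$signature_genes, seed = 1)
  planted <- names(s) %in% sim$truth$planted_high_cells
  p <- wilcox.test(s[planted], s[!planted], alternative = "greater")$p.value
  expect_lt(p, 1e-6)
})

test_that("score_all wraps the five scorers and drops unexpressed set genes harmlessly", {
  set.seed(64)
  m <- matrix(rpois(40 * 60, 4), 40, 60,
              dimnames = list(paste0("c", 1:40), paste0("g", 1:60)))
  cm <- count_matrix(m)
  set <- paste0("g", c(2, 13, 44))
  panel <- score_all(cm, set)
  expect_equal(nrow(panel), 40L)
  expect_named(panel, c("cell", "aucell", "ucell", "singscore", "ssgsea",
                        "module_score"))
  # an absent member changes none of the rank-based scores
  panel2 <- score_all(cm, c(set, "NOT_A_GENE"))
  expect_equal(panel2$aucell, panel$aucell)
  expect_equal(panel2$ucell, panel$ucell)
  expect_equal(panel2$singscore, panel$singscore)
  expect_equal(panel2$ssgsea, panel$ssgsea)
  # no member matched: missing scores with warning
  expect_warning(
    expect_warning(panel3 <- score_all(cm, c("X1", "X2")), "matched"),
    "no signature gene"
  )
  expect_true(all(is.na(panel3$aucell)))
})

test_that("worked examples survive the score_all wrapper", {
  # one cell realizing descending ranks 1..10 after lognorm (monotone)
  vals <- matrix(rep(10:1, each = 2), nrow = 2, byrow = FALSE,
                 dimnames = list(c("c1", "c2"), paste0("g", 1:10)))
  cm <- count_matrix(vals, layer = "counts")
  p <- score_all(cm, c("g3", "g6"),
                 scoring_params(auc_max_rank_fraction = 0.5, ucell_max_rank = 5))
  expect_equal(p$aucell[1], 1 / 3, tolerance = 1e-12)
  expect_equal(p$ucell[1], 0.4, tolerance = 1e-12)
  expect_equal(p$singscore[1], 0.625, tolerance = 1e-12)
})
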