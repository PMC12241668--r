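# A small cohort with strong planted effects, shared across selector tests.
planted_cohort <- function(seed = 35, n = 300, g = 25, n_info = 3,
                           effect = 1.5, censoring = 0.3) {
  simulate_cohort(sim_config(
    cohort_spec = list(n_samples = n, n_genes = g, n_informative = n_info,
                       effect_size = effect, censoring_rate = censoring),
    seed = seed
  ))
}

test_that("LASSO recovers planted genes, few false positives under the null, scale-invariant", {
  ch <- planted_cohort()
  sel <- select_lasso(ch$cohort, seed = 2, n_repeats = 3)
  expect_true(all(ch$truth$informative_genes %in% sel$selected))

  # doubling expression changes nothing (standardization)
  doubled <- ch$cohort
  gcols <- setdiff(names(doubled), c("sample_id", "label", "time", "event"))
  doubled[gcols] <- doubled[gcols] * 2
  sel2 <- select_lasso(doubled, seed = 2, n_repeats = 3)
  expect_equal(sel2$selected, sel$selected)

  null <- planted_cohort(seed = 36, effect = 0)
  picked <- lapply(1:4, function(s) {
    select_lasso(null$cohort, seed = s, n_repeats = 2)$selected
  })
  expect_lte(mean(lengths(picked)), 0.05 * 25 + 2)
  expect_error(select_lasso(dplyr::mutate(ch$cohort, label = 1)), "single class")
})

test_that("univariate Cox matches an established implementation on a 20-sample toy", {
  skip_if_not_installed("survival")
  set.seed(37)
  toy <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:20),
    label = rep(0:1, 10),
    time = round(rexp(20, 0.2), 2) + 0.1,
    event = rbinom(20, 1, 0.8),
    gA = rnorm(20), gB = rnorm(20)
  )
  toy$time[3] <- toy$time[4]  # force a tie
  mine <- select_unicox(toy)$diagnostics
  for (g in c("gA", "gB")) {
    ref <- survival::coxph(
      survival::Surv(time, event) ~ scale(toy[[g]]),
      data = toy, ties = "breslow"
    )
    row <- mine[mine$gene == g, ]
    expect_equal(row$log_hr, unname(coef(ref)), tolerance = 1e-6)
    expect_equal(row$se, unname(sqrt(vcov(ref)[1, 1])), tolerance = 1e-6)
  }
})

test_that("Cox recovers a planted log-hazard ratio and is calibrated under the null", {
  ch <- simulate_cohort(sim_config(
    cohort_spec = list(n_samples = 1000, n_genes = 3, n_informative = 1,
                       effect_size = 0.7, censoring_rate = 0.2),
    seed = 38
  ))
  d <- select_unicox(ch$cohort)$diagnostics
  b <- d$log_hr[d$gene == ch$truth$informative_genes]
  expect_lt(abs(b - 0.7) / 0.7, 0.15)

  null <- simulate_cohort(sim_config(
    cohort_spec = list(n_samples = 150, n_genes = 200, n_informative = 1,
                       effect_size = 0, censoring_rate = 0.2),
    seed = 39
  ))
  p <- select_unicox(null$cohort)$diagnostics$p
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
  no_events <- dplyr::mutate(ch$cohort, event = 0)
  expect_error(select_unicox(no_events), "no events")
})

test_that("random forest puts planted genes on top, noise importance near zero", {
  ch <- planted_cohort(seed = 40, n = 400)
  sel <- select_rf(ch$cohort, n_top = 20, seed = 3)
  expect_true(all(ch$truth$informative_genes %in% sel$selected))
  top3 <- sel$diagnostics$gene[1:3]
  expect_setequal(top3, ch$truth$informative_genes)
  noise_imp <- sel$diagnostics$importance[
    !sel$diagnostics$gene %in% ch$truth$informative_genes
  ]
  expect_lt(abs(mean(noise_imp)), 0.01)
  expect_equal(select_rf(ch$cohort, seed = 3)$selected, sel$selected)
})

test_that("Boruta confirms planted features and rejects noise", {
  ch <- planted_cohort(seed = 41, n = 500, g = 15)
  sel <- select_boruta(ch$cohort, max_iter = 40, seed = 4, n_trees = 150)
  expect_setequal(sel$selected, ch$truth$informative_genes)
  dec <- sel$diagnostics
  noise_dec <- dec$decision[!dec$gene %in% ch$truth$informative_genes]
  expect_gte(mean(noise_dec == "rejected"), 0.8)
  expect_equal(select_boruta(ch$cohort, max_iter = 40, seed = 4,
                             n_trees = 150)$selected, sel$selected)
  expect_error(select_boruta(ch$cohort, max_iter = 5), "at least 10")
})

test_that("a pure-shadow feature is rejected as iterations accumulate", {
  # label independent of every feature: hits behave like Bernoulli(<0.5)
  set.seed(42)
  ch <- planted_cohort(seed = 43, g = 8, effect = 0)
  sel <- select_boruta(ch$cohort, max_iter = 60, seed = 5, n_trees = 120)
  expect_length(sel$selected, 0)
  expect_gte(mean(sel$diagnostics$decision == "rejected"), 0.75)
})

test_that("gradient boosting concentrates gain on planted genes", {
  ch <- planted_cohort(seed = 44, n = 400)
  # gain concentration is a property of the signal-fitting rounds: measure it
  # before prolonged boosting starts spending splits on noise
  early <- select_xgb(ch$cohort, seed = 6, n_rounds = 10)
  d <- early$diagnostics
  planted_gain <- sum(d$gain[d$gene %in% ch$truth$informative_genes])
  expect_gt(planted_gain / sum(d$gain), 0.8)
  sel <- select_xgb(ch$cohort, seed = 6, n_rounds = 100)
  expect_true(all(ch$truth$informative_genes %in% sel$selected))
  expect_equal(select_xgb(ch$cohort, seed = 6, n_rounds = 100)$selected,
               sel$selected)
  topk <- select_xgb(ch$cohort, rule = "top_k", n_top = 5, seed = 6,
                     n_rounds = 100)
  expect_length(topk$selected, 5L)
})

test_that("the five-way intersection is contained in every list and finds the planted truth", {
  ch <- planted_cohort(seed = 45, n = 400, g = 20)
  rep5 <- select_features(
    ch$cohort, seed = 7,
    lasso = list(n_repeats = 2),
    rf = list(n_trees = 300),
    boruta = list(max_iter = 40, n_trees = 150),
    xgb = list(n_rounds = 100)
  )
  for (lst in rep5$selections) {
    expect_true(all(rep5$intersection %in% lst))
  }
  expect_setequal(rep5$intersection, ch$truth$informative_genes)
  td <- tidy(rep5)
  expect_true(all(td$gene[td$in_intersection] %in% rep5$intersection))
  g <- glance(rep5)
  expect_equal(g$n_intersection, length(rep5$intersection))

  expect_equal(intersect_selections(list(a = c("x", "y"), b = character(0))),
               character(0))
  expect_equal(intersect_selections(list(a = c("x", "y"), b = c("x", "y"))),
               c("x", "y"))
})
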