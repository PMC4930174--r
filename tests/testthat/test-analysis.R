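test_that("group cooperation rates match hand counts on fixtures", {
  fix <- fixture_half_dataset()
  expect_equal(group_cooperation_rate(fix, "fix.atomized.g01", 1, 3), 0.5)
  expect_equal(group_cooperation_rate(fix, "fix.atomized.g01", 2, 2), 0.5)
  all_c <- fix
  all_c$action_a <- "C"; all_c$action_b <- "C"
  expect_equal(group_cooperation_rate(all_c, "fix.atomized.g01", 1, 3), 1)
  expect_error(group_cooperation_rate(fix, "fix.atomized.g01", 4, 9),
               "no records")
  # traced cascade: atomized injection run, rate = 1 - defections/total
  rec <- run_group(group_config(condition = "atomized"),
                   strategies = strategy_spec("TRIGGER"), seed = 42,
                   inject = list(period = 1, actor = 1))
  ds <- data.frame(experiment = "t", group = "g1", condition = "atomized",
                   rec[, c("period", "actor_a", "actor_b", "action_a",
                           "action_b", "payoff_a", "payoff_b")])
  w <- ds[ds$period <= 35, ]
  hand <- 1 - sum(c(w$action_a, w$action_b) == "D") / (2 * nrow(w))
  expect_equal(group_cooperation_rate(ds, "g1", 1, 35), hand)
})

test_that("first-interaction rates follow the dyad-first-encounter definition", {
  fix <- fixture_half_dataset()
  # 3 cooperators + 3 defectors, all 15 dyads eventually matched:
  # 15 of the 30 first-encounter actions are C
  expect_equal(first_interaction_cooperation(fix, "fix.atomized.g01"), 0.5)
  # dyad-level: only the 3 dyads among the cooperators are jointly C
  expect_equal(first_interaction_cooperation(fix, "fix.atomized.g01",
                                             level = "dyad"), 3 / 15)
  # all-trigger noiseless group opens with cooperation everywhere
  rec <- run_group(group_config(condition = "embedded"),
                   strategies = strategy_spec("TRIGGER"), seed = 3)
  ds <- data.frame(experiment = "t", group = "g1", condition = "embedded",
                   rec[, c("period", "actor_a", "actor_b", "action_a",
                           "action_b", "payoff_a", "payoff_b")])
  expect_equal(first_interaction_cooperation(ds, "g1"), 1)
  rec_d <- run_group(group_config(), strategies = strategy_spec("ALL_D"), seed = 3)
  ds_d <- data.frame(experiment = "t", group = "g1", condition = "atomized",
                     rec_d[, c("period", "actor_a", "actor_b", "action_a",
                               "action_b", "payoff_a", "payoff_b")])
  expect_equal(first_interaction_cooperation(ds_d, "g1"), 0)
})

test_that("exact Mann-Whitney matches enumeration and wilcox.test", {
  # complete separation of 3 vs 3, one-sided: p = 1/C(6,3) = 1/20
  t1 <- mann_whitney(c(0.9, 0.8, 0.7), c(0.2, 0.3, 0.4), "greater")
  expect_equal(t1$p_value, 0.05)
  expect_equal(t1$statistic, 9)  # all 9 pairs won
  # identical constant samples: no separation, p = 1, flagged degenerate
  t2 <- mann_whitney(rep(0.5, 4), rep(0.5, 4))
  expect_equal(t2$p_value, 1)
  expect_true(t2$degenerate)
  # oracle equivalence on random small samples, with and without ties
  set.seed(6001)
  for (i in 1:30) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    vals <- if (i %% 2 == 0) round(stats::runif(na + nb), 1) else stats::runif(na + nb)
    a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
    for (alt in c("two.sided", "greater", "less")) {
      expect_equal(mann_whitney(a, b, alt)$p_value, oracle_mw_exact(a, b, alt),
                   tolerance = 1e-12)
    }
    # tie-free cases also agree with stats::wilcox.test's exact p
    if (!any(duplicated(vals))) {
      wt <- stats::wilcox.test(a, b, exact = TRUE)
      expect_equal(mann_whitney(a, b)$p_value, wt$p.value, tolerance = 1e-12)
    }
  }
})

test_that("large-sample Mann-Whitney uses the tie-corrected normal tail", {
  set.seed(6002)
  a <- stats::runif(15); b <- stats::runif(15) + 0.2
  t_norm <- mann_whitney(a, b)  # N = 30 > 20: approximation path
  wt <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(t_norm$p_value, wt$p.value, tolerance = 1e-6)
  expect_match(t_norm$method, "normal approximation")
})

test_that("variance comparison reproduces hand-computed F ratios", {
  a <- c(0.50, 0.62, 0.31, 0.49)
  b <- c(0.42, 0.44, 0.47, 0.43)
  vt <- variance_comparison(a, b, "greater")
  expect_equal(vt$statistic, stats::var(a) / stats::var(b))
  expect_equal(vt$p_value,
               stats::pf(stats::var(a) / stats::var(b), 3, 3, lower.tail = FALSE))
  # identical arms: ratio 1, one-sided p exactly 1/2 by symmetry
  vt1 <- variance_comparison(c(1, 2, 3), c(1, 2, 3), "greater")
  expect_equal(vt1$statistic, 1)
  expect_equal(vt1$p_value, 0.5)
  expect_error(variance_comparison(c(1, 1, 1), a, "greater"), "degenerate")
  # doubling the SD becomes detectable as samples grow
  set.seed(6003)
  p_small <- variance_comparison(stats::rnorm(6, sd = 2), stats::rnorm(6), "greater")$p_value
  p_large <- variance_comparison(stats::rnorm(60, sd = 2), stats::rnorm(60), "greater")$p_value
  expect_lt(p_large, 0.01)
  expect_lt(p_large, p_small)
  # the permutation variant agrees with F to first order on normal data
  x <- stats::rnorm(10, sd = 1.5); y <- stats::rnorm(10)
  pf_ <- variance_comparison(x, y, "greater")$p_value
  pp_ <- variance_comparison(x, y, "greater", method = "permutation",
                             n_perm = 4000, seed = 8)$p_value
  expect_lt(abs(pf_ - pp_), 0.12)
})

test_that("t-test power follows the noncentral-t form and Monte-Carlo", {
  expect_equal(t_test_power(0, sd = 0.1, n = 5), 0.05)
  p1 <- t_test_power(0.19, 0.1, 5)
  expect_gte(p1, 0.80)
  # direct noncentral-t evaluation
  ncp <- 0.19 / 0.1 * sqrt(5 / 2)
  crit <- stats::qt(0.95, df = 8)
  expect_equal(p1, 1 - stats::pt(crit, df = 8, ncp = ncp), tolerance = 1e-6)
  # Monte-Carlo oracle within 3 sigma
  set.seed(6004)
  reps <- 20000
  rej <- sum(vapply(seq_len(reps), function(i) {
    x <- stats::rnorm(5, 0.19, 0.1); y <- stats::rnorm(5, 0, 0.1)
    stats::t.test(x, y, alternative = "greater", var.equal = TRUE)$p.value <= 0.05
  }, logical(1)))
  mc <- rej / reps
  expect_lt(abs(p1 - mc), 3 * sqrt(mc * (1 - mc) / reps))
  expect_error(t_test_power(-1, 0.1, 5), ">= 0")
})

test_that("the hypothesis suite is pure and degenerate-aware", {
  d <- generate_experiment(experiment_design("exp2",
         mixture = strategy_mixture(TRIGGER = 1, tremble = 0.05), seed = 13))
  r1 <- run_hypothesis_suite(d)
  r2 <- run_hypothesis_suite(d)
  expect_identical(report_json(r1), report_json(r2))
  expect_named(r1$experiments, "exp2")
  expect_equal(r1$pooled$n_embedded, 6)
  # an all-C dataset: rates all 1, tests flagged degenerate, no errors
  dc <- generate_experiment(experiment_design("exp2",
          mixture = strategy_mixture(ALL_C = 1), endgame_max = 0, seed = 13))
  rc <- run_hypothesis_suite(dc)
  expect_equal(rc$group_stats$coop_rate_main, rep(1, 12))
  expect_true(rc$pooled$h1$degenerate)
  expect_equal(rc$pooled$h1$p_value, 1)
  expect_true(rc$pooled$end_window$variance_test$degenerate)
})

test_that("window 1-40 equals window 1-35 when behavior is horizon-free", {
  # deterministic strategies, no endgame ramp: per-period rates are constant
  d <- generate_experiment(experiment_design("exp2",
         mixture = strategy_mixture(ALL_C = 0.5, ALL_D = 0.5),
         endgame_max = 0, seed = 17))
  for (g in unique(d$group)) {
    expect_equal(group_cooperation_rate(d, g, 1, 40),
                 group_cooperation_rate(d, g, 1, 35))
  }
})

test_that("a real difference between arms is detected with one-sided H1", {
  # build a dataset whose embedded arm cooperates more by construction
  lo <- generate_experiment(experiment_design("exp1",
          mixture = strategy_mixture(ALL_C = 0.3, ALL_D = 0.7),
          endgame_max = 0, seed = 19))
  hi <- generate_experiment(experiment_design("exp1",
          mixture = strategy_mixture(ALL_C = 0.9, ALL_D = 0.1),
          endgame_max = 0, seed = 23))
  d <- rbind(lo[lo$condition == "atomized", ], hi[hi$condition == "embedded", ])
  rep <- run_hypothesis_suite(d, alternative = "greater")
  expect_lt(rep$pooled$h1$p_value, 0.05)
  # and with more groups the evidence sharpens
  lo2 <- generate_experiment(experiment_design("custom", groups_per_condition = 14,
           mixture = strategy_mixture(ALL_C = 0.3, ALL_D = 0.7),
           endgame_max = 0, seed = 19))
  hi2 <- generate_experiment(experiment_design("custom", groups_per_condition = 14,
           mixture = strategy_mixture(ALL_C = 0.9, ALL_D = 0.1),
           endgame_max = 0, seed = 23))
  d2 <- rbind(lo2[lo2$condition == "atomized", ], hi2[hi2$condition == "embedded", ])
  rep2 <- run_hypothesis_suite(d2, alternative = "greater")
  expect_lt(rep2$pooled$h1$p_value, rep$pooled$h1$p_value)
})

test_that("missing condition arms are rejected with a clear error", {
  d <- generate_experiment(experiment_design("exp2", seed = 1))
  expect_error(run_hypothesis_suite(d[d$condition == "atomized", ]),
               "both an atomized and an embedded arm")
})
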