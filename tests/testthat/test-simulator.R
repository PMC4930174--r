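test_that("decide follows the strategy definitions", {
  trig <- strategy_spec("TRIGGER")
  none <- list(seen_defect = rep(FALSE, 6))
  expect_equal(decide(1, 2, trig, none), "C")  # initial cooperation
  # partner seen defecting (against anyone within scope) -> defect forever
  seen2 <- list(seen_defect = c(FALSE, TRUE, rep(FALSE, 4)))
  expect_equal(decide(1, 2, trig, seen2), "D")
  # a third actor's defection does not trigger the plain trigger...
  seen3 <- list(seen_defect = c(FALSE, FALSE, TRUE, rep(FALSE, 3)))
  expect_equal(decide(1, 2, trig, seen3), "C")
  # ...but does trigger the strong trigger
  expect_equal(decide(1, 2, strategy_spec("STRONG_TRIGGER"), seen3), "D")
  expect_equal(decide(1, 2, strategy_spec("ALL_C"), seen2), "C")
  expect_equal(decide(1, 2, strategy_spec("ALL_D"), none), "D")
  # learning: propensity 1 always cooperates, 0 never
  lrn <- strategy_spec("LEARNING")
  expect_equal(decide(1, 2, lrn, list(seen_defect = none$seen_defect,
                                      propensity = rep(1, 6))), "C")
  expect_equal(decide(1, 2, lrn, list(seen_defect = none$seen_defect,
                                      propensity = rep(0, 6))), "D")
})

test_that("trembles flip intended actions at the nominal rate", {
  expect_equal(apply_tremble(rep("C", 100), 0), rep("C", 100))
  set.seed(5001)
  for (rate in c(0.5, 0.05)) {
    n <- 1e5
    flips <- sum(apply_tremble(rep("C", n), rate) == "D")
    expect_lt(abs(flips / n - rate), 3 * sqrt(rate * (1 - rate) / n))
  }
  expect_error(apply_tremble("C", 1), "\\[0, 1\\)")
})

test_that("identical seeds give bit-identical runs; different seeds differ", {
  cfg <- group_config(condition = "embedded")
  st <- strategy_spec("TRIGGER", tremble = 0.05)
  r1 <- run_group(cfg, strategies = st, seed = 99)
  r2 <- run_group(cfg, strategies = st, seed = 99)
  expect_identical(r1, r2)
  r3 <- run_group(cfg, strategies = st, seed = 100)
  expect_false(identical(r1$action_a, r3$action_a))
})

test_that("run_group respects the structural contract of the record format", {
  cfg <- group_config()
  rec <- run_group(cfg, strategies = strategy_spec("LEARNING"), seed = 5)
  expect_equal(nrow(rec), 40 * 6)         # n*m/2 dyads per period
  expect_true(all(table(rec$period) == 6))
  expect_true(all(rec$actor_a < rec$actor_b))
  # payoffs consistent with the stage game on realized actions
  pay <- dyad_payoff(rec$action_a, rec$action_b)
  expect_equal(rec$payoff_a, unname(pay[, "i"]))
  expect_equal(rec$payoff_b, unname(pay[, "j"]))
  # every actor matched exactly m times per period
  for (t in c(1, 20, 40)) {
    rt <- rec[rec$period == t, ]
    expect_equal(unname(tabulate(c(rt$actor_a, rt$actor_b), 6)), rep(2L, 6))
  }
})

test_that("homogeneous deterministic groups hit the boundary rates", {
  for (cond in c("atomized", "embedded")) {
    cfg <- group_config(condition = cond)
    rec_c <- run_group(cfg, strategies = strategy_spec("TRIGGER"), seed = 1)
    expect_equal(unname(cooperation_trajectory(rec_c)), rep(1, 40))
    rec_d <- run_group(cfg, strategies = strategy_spec("ALL_D"), seed = 1)
    expect_equal(unname(cooperation_trajectory(rec_d)), rep(0, 40))
  }
})

test_that("a single injected defection collapses an embedded trigger group", {
  cfg <- group_config(condition = "embedded")
  rec <- run_group(cfg, strategies = strategy_spec("TRIGGER"), seed = 42,
                   inject = list(period = 1, actor = 1))
  traj <- cooperation_trajectory(rec)
  # exactly one defection in period 1, by actor 1
  p1 <- rec[rec$period == 1, ]
  d1 <- c(p1$action_a, p1$action_b) == "D"
  expect_equal(sum(d1), 1)
  # the retaliation cascade: trajectory weakly decreasing to all-D
  expect_true(all(diff(traj) <= 1e-12))
  expect_equal(unname(traj[40]), 0)
  # period 2: everyone who meets actor 1 defects on him (all are informed)
  p2 <- rec[rec$period == 2, ]
  vs1 <- p2[p2$actor_a == 1 | p2$actor_b == 1, ]
  partner_action <- ifelse(vs1$actor_a == 1, vs1$action_b, vs1$action_a)
  expect_true(all(partner_action == "D"))
})

test_that("the same injection under atomized information stays in one dyad", {
  cfg <- group_config(condition = "atomized")
  rec <- run_group(cfg, strategies = strategy_spec("TRIGGER"), seed = 42,
                   inject = list(period = 1, actor = 1))
  p1 <- rec[rec$period == 1, ]
  hit <- p1[(p1$actor_a == 1 & p1$action_a == "D") |
              (p1$actor_b == 1 & p1$action_b == "D"), ]
  expect_equal(nrow(hit), 1)
  partner <- ifelse(hit$actor_a == 1, hit$actor_b, hit$actor_a)
  # all defections across the whole run are confined to the dyad {1, partner}
  defe <- rec[rec$action_a == "D" | rec$action_b == "D", ]
  expect_gt(nrow(defe), 1)
  expect_true(all(pmin(defe$actor_a, defe$actor_b) == 1))
  expect_true(all(pmax(defe$actor_a, defe$actor_b) == partner))
  # the other 14 dyads cooperate throughout
  other <- rec[!(rec$actor_a %in% c(1, partner) & rec$actor_b %in% c(1, partner)), ]
  expect_true(all(other$action_a == "C" & other$action_b == "C"))
})

test_that("decisions in period t use only information through t-1", {
  # under embedded information, retaliation against an injected defection
  # starts exactly one period later, never in the same period
  cfg <- group_config(condition = "embedded")
  for (tstar in c(1, 5, 17)) {
    rec <- run_group(cfg, strategies = strategy_spec("TRIGGER"), seed = 7,
                     inject = list(period = tstar, actor = 3))
    before <- rec[rec$period <= tstar, ]
    expect_equal(sum(c(before$action_a, before$action_b) == "D"), 1)
    after <- rec[rec$period == tstar + 1, ]
    expect_gt(sum(c(after$action_a, after$action_b) == "D"), 1)
  }
})

test_that("strategies have no horizon knowledge: no endgame decline", {
  cfg <- group_config(condition = "embedded")
  rec <- run_group(cfg, strategies = strategy_spec("TRIGGER"), seed = 12)
  traj <- cooperation_trajectory(rec)
  expect_equal(unname(traj[36:40]), rep(1, 5))
  # learning agents likewise show no systematic final-five drop
  recl <- run_group(group_config(), strategies = strategy_spec("LEARNING"),
                    seed = 12)
  trajl <- cooperation_trajectory(recl)
  expect_gt(mean(trajl[36:40]), mean(trajl[1:35]) - 0.35)
})

test_that("intended vs realized actions are both recorded under noise", {
  cfg <- group_config(condition = "atomized")
  rec <- run_group(cfg, strategies = strategy_spec("ALL_C", tremble = 0.2),
                   seed = 31)
  expect_true(all(rec$intended_a == "C" & rec$intended_b == "C"))
  flips <- sum(rec$action_a == "D") + sum(rec$action_b == "D")
  expect_gt(flips, 0)
  ci <- stats::binom.test(flips, 2 * nrow(rec), p = 0.2)$conf.int
  expect_true(ci[1] <= 0.2 && 0.2 <= ci[2])
})

test_that("noise hurts embedded groups more than atomized groups", {
  # directional check at modest scale; the full 500-seed one-sided test
  # lives with the acceptance checks
  st <- strategy_spec("TRIGGER", tremble = 0.02)
  seeds <- 1:60
  emb <- vapply(seeds, function(s) {
    mean(cooperation_trajectory(run_group(group_config(condition = "embedded"),
                                          strategies = st, seed = s))[1:35])
  }, numeric(1))
  ato <- vapply(seeds, function(s) {
    mean(cooperation_trajectory(run_group(group_config(condition = "atomized"),
                                          strategies = st, seed = 1000 + s))[1:35])
  }, numeric(1))
  expect_lt(stats::t.test(emb, ato, alternative = "less")$p.value, 0.01)
})

test_that("discriminating triggers forgive observed retaliation", {
  # embedded group, one injected defection: a discriminating trigger keeps
  # cooperating with the retaliators, so cooperation does not collapse to 0
  cfg <- group_config(condition = "embedded")
  st <- strategy_spec("TRIGGER", discriminating = TRUE)
  rec <- run_group(cfg, strategies = st, seed = 42,
                   inject = list(period = 1, actor = 1))
  traj <- cooperation_trajectory(rec)
  expect_gt(unname(traj[40]), 0.5)
})
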