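# Independent oracles and fixtures. These deliberately re-derive quantities
# by a different route than the package implementation.

# Truncated-series evaluation of the three expected utilities, summing the
# displayed per-period terms directly. Tail bound for the discarded part:
# sup-payoff * beta^H / (1 - beta).
oracle_eu_series <- function(payoffs, n, m, beta, horizon = 1e4) {
  t <- seq_len(horizon)
  disc <- beta^(t - 1)
  base <- (n - 1 - m) * payoffs$Q
  p <- m / (n - 1)
  all_c <- sum(disc * (m * payoffs$R + base))
  all_d_emb <- sum(disc * c(m * payoffs$T + base,
                            rep(m * payoffs$P + base, horizon - 1L)))
  per_rel <- p * (1 - p)^(t - 1) * payoffs$T +
    p * (1 - (1 - p)^(t - 1)) * payoffs$P +
    (1 - p) * payoffs$Q
  all_d_ato <- (n - 1) * sum(disc * per_rel)
  c(all_c = all_c, all_d_embedded = all_d_emb, all_d_atomized = all_d_ato)
}

# Monte-Carlo relation-activation oracle for EU(ALL-D | atomized): simulate
# each of the n-1 independent relations' activation sequences; a relation
# pays T at its first activation, P at later activations, Q when inactive.
# Returns the estimate and its standard error.
oracle_eu_atomized_mc <- function(payoffs, n, m, beta, reps = 40000,
                                  horizon = 300) {
  p <- m / (n - 1)
  disc <- beta^(seq_len(horizon) - 1)
  vals <- vapply(seq_len(reps), function(i) {
    act <- stats::runif(horizon) < p
    first <- match(TRUE, act)
    pay <- ifelse(act, payoffs$P, payoffs$Q)
    if (!is.na(first)) pay[first] <- payoffs$T
    sum(disc * pay)
  }, numeric(1))
  est <- (n - 1) * mean(vals)
  se <- (n - 1) * stats::sd(vals) / sqrt(reps)
  # truncation bias bound on the per-relation tail
  tail_bound <- (n - 1) * max(abs(unlist(payoffs))) * beta^horizon / (1 - beta)
  list(estimate = est, se = se, tail = tail_bound)
}

# Random valid model parameterization. Payoffs are O(100) points so that
# absolute indifference-gap tolerances of 1e-9 are meaningful for doubles.
rand_params <- function() {
  pays <- sort(stats::runif(4, 0, 100))
  repeat {
    n <- sample(3:8, 1)
    m <- sample(seq_len(n - 1), 1)
    if ((n * m) %% 2 == 0) break
  }
  list(payoffs = pd_payoffs(T = pays[4], R = pays[3], P = pays[2], S = pays[1],
                            Q = stats::runif(1, 0, 100)),
       n = n, m = m, beta = stats::runif(1, 0.05, 0.9))
}

# Brute-force exact Mann-Whitney p-value by enumerating all assignments of
# the pooled VALUES to the first arm and counting pairwise wins (+ half
# ties) -- a different route than the implementation's midrank sums.
oracle_mw_exact <- function(a, b, alternative = "two.sided") {
  na <- length(a); nb <- length(b)
  pool <- c(a, b)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_of(a, b)
  splits <- utils::combn(na + nb, na)
  u_all <- apply(splits, 2, function(idx) u_of(pool[idx], pool[-idx]))
  p_ge <- mean(u_all >= u_obs - 1e-9)
  p_le <- mean(u_all <= u_obs + 1e-9)
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# Deterministic hand-built 6-actor dataset: three periods whose 2-regular
# matchings jointly cover all 15 dyads exactly once-or-more; each actor
# always plays its type's action (actors 1-3 cooperate, 4-6 defect).
fixture_half_dataset <- function(payoffs = pd_payoffs()) {
  per_edges <- list(
    rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6), c(1, 6)),
    rbind(c(1, 3), c(2, 4), c(3, 5), c(4, 6), c(1, 5), c(2, 6)),
    rbind(c(1, 4), c(2, 5), c(3, 6), c(1, 5), c(2, 6), c(3, 4)))
  rows <- do.call(rbind, lapply(seq_along(per_edges), function(t) {
    e <- per_edges[[t]]
    data.frame(experiment = "fix", group = "fix.atomized.g01",
               condition = "atomized", period = t,
               actor_a = pmin(e[, 1], e[, 2]), actor_b = pmax(e[, 1], e[, 2]),
               stringsAsFactors = FALSE)
  }))
  rows$action_a <- ifelse(rows$actor_a <= 3, "C", "D")
  rows$action_b <- ifelse(rows$actor_b <= 3, "C", "D")
  pay <- dyad_payoff(rows$action_a, rows$action_b, payoffs)
  rows$payoff_a <- pay[, "i"]; rows$payoff_b <- pay[, "j"]
  rows
}

# Per-group cooperation rates of a dataset, split by condition.
rates_by_condition <- function(dataset, lo = 1, hi = 35) {
  groups <- unique(dataset$group)
  r <- vapply(groups, function(g) group_cooperation_rate(dataset, g, lo, hi),
              numeric(1))
  cond <- vapply(groups, function(g) dataset$condition[match(g, dataset$group)],
                 character(1))
  split(unname(r), cond)
}
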