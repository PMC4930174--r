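#' Reputation model for cooperation on a small complete network
#'
#' Construct the game-theoretic model of conditional cooperation in repeated
#' two-person Prisoner's Dilemmas played within an `n`-actor complete
#' network, where each actor is matched with exactly `m` partners per period.
#' The fitted object carries the two threshold discount factors above which
#' mutual trigger-strategy play is a Nash equilibrium: `beta_emb` when all
#' interactions are observed by everyone (embedded information, the
#' reputation channel) and `beta_ato` when actors observe only their own
#' interactions (atomized information). `beta_ato >= beta_emb` always, with
#' equality exactly when `m = n - 1`: reputation weakens the condition for
#' cooperation.
#'
#' @param payoffs A [pd_payoffs()] object.
#' @inheritParams group_config
#' @return An object of class `"rw_model"` with components `payoffs`, `n`,
#'   `m`, `pi` (the per-period matching probability of a dyad), `beta_emb`,
#'   and `beta_ato`.
#' @seealso [predict.rw_model()] for expected utilities at a stated discount
#'   factor, [simulate.rw_model()] for agent-based play of the same game,
#'   [beta_threshold_embedded()], [beta_threshold_atomized()].
#' @examples
#' mod <- rw_model()
#' mod
#' coef(mod)          # beta_emb = 1/2, beta_ato = 5/7, pi = 0.4
#' predict(mod, beta = c(0.5, 5 / 7))
#' @export
rw_model <- function(payoffs = pd_payoffs(), n = 6, m = 2) {
  payoffs <- as_pd_payoffs(payoffs)
  check_n_m(n, m)
  structure(list(payoffs = payoffs,
                 n = as.integer(n),
                 m = as.integer(m),
                 pi = interaction_probability(n, m),
                 beta_emb = beta_threshold_embedded(payoffs),
                 beta_ato = beta_threshold_atomized(payoffs, n, m)),
            class = "rw_model")
}

#' @export
print.rw_model <- function(x, digits = 4, ...) {
  cat("Repeated Prisoner's Dilemma on a complete network\n")
  print(x$payoffs)
  cat(sprintf("  n = %d actors, m = %d partners/period, pi = m/(n-1) = %s\n",
              x$n, x$m, format(x$pi, digits = digits)))
  cat("Threshold discount factors for conditional cooperation:\n")
  cat(sprintf("  embedded information:  beta_emb = %s\n",
              format(x$beta_emb, digits = digits)))
  cat(sprintf("  atomized information:  beta_ato = %s\n",
              format(x$beta_ato, digits = digits)))
  invisible(x)
}

#' @export
coef.rw_model <- function(object, ...) {
  c(beta_emb = object$beta_emb, beta_ato = object$beta_ato, pi = object$pi)
}

#' Expected utilities of the model at stated discount factors
#'
#' Evaluate the discounted expected utilities of unconditional cooperation
#' and of defection (under each information regime) against trigger-strategy
#' opponents, together with the signed cooperation premia.
#'
#' @param object An [rw_model()] object.
#' @param beta Discount factor(s) in (0, 1).
#' @param ... Unused.
#' @return A data frame with one row per `beta`: columns `beta`, `eu_all_c`,
#'   `eu_all_d_embedded`, `eu_all_d_atomized`, `gap_embedded`,
#'   `gap_atomized`. A gap is positive exactly when `beta` exceeds the
#'   corresponding threshold.
#' @examples
#' predict(rw_model(), beta = c(0.4, 0.5, 5 / 7, 0.9))
#' @export
predict.rw_model <- function(object, beta, ...) {
  check_beta(beta)
  p <- object$payoffs; n <- object$n; m <- object$m
  euc <- eu_all_c(p, n, m, beta)
  eue <- eu_all_d_embedded(p, n, m, beta)
  eua <- eu_all_d_atomized(p, n, m, beta)
  data.frame(beta = beta, eu_all_c = euc,
             eu_all_d_embedded = eue, eu_all_d_atomized = eua,
             gap_embedded = euc - eue, gap_atomized = euc - eua)
}

#' @export
summary.rw_model <- function(object, ...) {
  structure(list(model = object,
                 at_thresholds = rbind(
                   predict(object, beta = object$beta_emb),
                   predict(object, beta = object$beta_ato))),
            class = "summary.rw_model")
}

#' @export
print.summary.rw_model <- function(x, digits = 4, ...) {
  print(x$model, digits = digits)
  cat("\nExpected utilities at the thresholds:\n")
  print(x$at_thresholds, digits = digits, row.names = FALSE)
  cat("\n(gap_embedded = 0 at beta_emb; gap_atomized = 0 at beta_ato)\n")
  invisible(x)
}

#' Plot the expected-utility curves of the model
#'
#' Discounted expected utilities of ALL-C and of ALL-D under both information
#' regimes as functions of the discount factor, with the two thresholds
#' marked. The ALL-C curve crosses each ALL-D curve exactly at the
#' corresponding threshold.
#'
#' @param x An [rw_model()] object.
#' @param beta_range Range of discount factors displayed.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.rw_model <- function(x, beta_range = c(0.05, 0.95), ...) {
  beta <- seq(beta_range[1L], beta_range[2L], length.out = 200L)
  pr <- predict(x, beta)
  graphics::matplot(beta, as.matrix(pr[, c("eu_all_c", "eu_all_d_embedded",
                                           "eu_all_d_atomized")]),
                    type = "l", lty = c(1, 2, 3), col = c(1, 2, 4),
                    xlab = expression(beta), ylab = "discounted points", ...)
  graphics::abline(v = c(x$beta_emb, x$beta_ato), col = "grey60", lty = 4)
  graphics::legend("topleft",
                   legend = c("ALL-C", "ALL-D | embedded", "ALL-D | atomized",
                              "thresholds"),
                   lty = c(1, 2, 3, 4), col = c(1, 2, 4, "grey60"), bty = "n")
  invisible(x)
}

#' Simulate agent-based play of the model's game
#'
#' Play the model's repeated game with software agents: per-period uniform
#' m-regular matching, simultaneous decisions, optional tremble noise, under
#' either information regime. A thin wrapper around [run_group()].
#'
#' @param object An [rw_model()] object.
#' @param nsim Number of independent group runs.
#' @param seed Integer seed; run `i` uses a seed derived from `seed` and `i`,
#'   so adding runs does not perturb existing ones.
#' @param condition Information regime for all runs.
#' @param periods Periods per run.
#' @param strategies A [strategy_spec()] (recycled to all actors) or a list
#'   of one spec per actor.
#' @param ... Passed to [run_group()].
#' @return A list of `nsim` simulation record data frames (see
#'   [run_group()]); a single data frame if `nsim = 1`.
#' @examples
#' mod <- rw_model()
#' rec <- simulate(mod, seed = 1, condition = "embedded")
#' mean(cooperation_trajectory(rec))
#' @export
simulate.rw_model <- function(object, nsim = 1, seed = NULL,
                              condition = c("atomized", "embedded"),
                              periods = 40,
                              strategies = strategy_spec("TRIGGER"), ...) {
  condition <- match.arg(condition)
  cfg <- group_config(n = object$n, m = object$m, periods = periods,
                      condition = condition)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  runs <- lapply(seq_len(nsim), function(i) {
    run_group(cfg, object$payoffs, strategies,
              seed = derive_seed(seed, i), ...)
  })
  if (nsim == 1L) runs[[1L]] else runs
}
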