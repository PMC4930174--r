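#' Strategy specification for simulated actors
#'
#' Define how a software agent plays the repeated game.
#'
#' * `ALL_C` / `ALL_D`: unconditional cooperation / defection.
#' * `TRIGGER`: cooperate with a partner until *that partner* is observed
#'   defecting against anyone within the actor's information scope, then
#'   defect against that partner forever. Under atomized information the
#'   scope is the actor's own interactions; under embedded information it is
#'   all interactions in the group.
#' * `STRONG_TRIGGER`: defect against everyone forever after observing any
#'   defection by any other actor (within scope).
#' * `LEARNING`: backward-looking Bush-Mosteller reinforcement. Each
#'   directed dyad carries a propensity to cooperate, initialized at `init`;
#'   after each interaction the propensity of the action just played is
#'   reinforced (weakened) in proportion to `rate` times the positive
#'   (negative) normalized distance of the realized payoff from the
#'   aspiration level. This is one standard reading of aspiration-based
#'   learning, not a calibrated behavioral claim.
#'
#' `tremble` is implementation noise: independently for every decision, the
#' intended action is flipped with probability `tremble` (symmetric in both
#' directions).
#'
#' @param kind Strategy kind; see Details.
#' @param tremble Per-decision error probability in `[0, 1)`.
#' @param discriminating For `TRIGGER`/`STRONG_TRIGGER`: if `TRUE`, observed
#'   defections that are themselves retaliation against a defection the
#'   defector had already observed do not trigger. Default `FALSE`: any
#'   observed defection triggers, including retaliation.
#' @param aspiration For `LEARNING`: aspiration level as a fraction of the
#'   payoff range, i.e. the aspiration in points is `S + aspiration * (T - S)`
#'   (default 0.5, which is 30 points under the default payoffs).
#' @param rate For `LEARNING`: update rate in `[0, 1]`.
#' @param init For `LEARNING`: initial cooperation propensity in `[0, 1]`.
#' @return An object of class `"strategy_spec"`.
#' @examples
#' strategy_spec("TRIGGER")
#' strategy_spec("TRIGGER", tremble = 0.02)
#' strategy_spec("LEARNING", rate = 0.5, aspiration = 0.5)
#' @export
strategy_spec <- function(kind = c("TRIGGER", "ALL_C", "ALL_D",
                                   "STRONG_TRIGGER", "LEARNING"),
                          tremble = 0, discriminating = FALSE,
                          aspiration = 0.5, rate = 0.5, init = 0.5) {
  kind <- match.arg(kind)
  if (!is.numeric(tremble) || length(tremble) != 1L || tremble < 0 || tremble >= 1) {
    stop("`tremble` must lie in [0, 1)", call. = FALSE)
  }
  for (nm in c("aspiration", "rate", "init")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      stop(sprintf("`%s` must lie in [0, 1]", nm), call. = FALSE)
    }
  }
  structure(list(kind = kind, tremble = tremble,
                 discriminating = isTRUE(discriminating),
                 aspiration = aspiration, rate = rate, init = init),
            class = "strategy_spec")
}

#' @export
print.strategy_spec <- function(x, ...) {
  extra <- if (x$kind == "LEARNING") {
    sprintf(", aspiration = %g, rate = %g, init = %g", x$aspiration, x$rate, x$init)
  } else if (x$discriminating) ", discriminating" else ""
  cat(sprintf("Strategy: %s (tremble = %g%s)\n", x$kind, x$tremble, extra))
  invisible(x)
}

#' One actor's intended action toward one partner
#'
#' Evaluate a strategy against the actor's current information state,
#' returning the *intended* action (before any tremble).
#'
#' @param actor,partner Actor indices in `1..n`.
#' @param strategy A [strategy_spec()].
#' @param info The actor's information view: a list with components
#'   `seen_defect` (logical vector of length `n`; element `j` is `TRUE` if
#'   the actor has observed actor `j` defect, within the actor's information
#'   scope and, for discriminating triggers, already filtered to
#'   non-retaliatory defections) and, for `LEARNING`, `propensity` (numeric
#'   vector of length `n` of per-partner cooperation propensities).
#' @return `"C"` or `"D"`. `LEARNING` draws from the R random number
#'   generator.
#' @examples
#' info <- list(seen_defect = rep(FALSE, 6))
#' decide(1, 2, strategy_spec("TRIGGER"), info)  # "C": empty history
#' info$seen_defect[2] <- TRUE
#' decide(1, 2, strategy_spec("TRIGGER"), info)  # "D": partner seen defecting
#' @export
decide <- function(actor, partner, strategy, info) {
  switch(strategy$kind,
         ALL_C = "C",
         ALL_D = "D",
         TRIGGER = if (isTRUE(info$seen_defect[partner])) "D" else "C",
         STRONG_TRIGGER =
           if (any(info$seen_defect[-actor])) "D" else "C",
         LEARNING =
           if (stats::runif(1L) < info$propensity[partner]) "C" else "D")
}

#' Apply tremble noise to intended actions
#'
#' Each intended action is flipped (C to D, D to C) independently with
#' probability `tremble`.
#'
#' @param action Character vector of intended actions (`"C"`/`"D"`).
#' @param tremble Flip probability in `[0, 1)`; recycled over `action`.
#' @return Character vector of realized actions.
#' @examples
#' set.seed(1)
#' apply_tremble(rep("C", 10), tremble = 0.5)
#' @export
apply_tremble <- function(action, tremble) {
  if (any(tremble < 0 | tremble >= 1)) stop("`tremble` must lie in [0, 1)", call. = FALSE)
  flip <- stats::runif(length(action)) < tremble
  ifelse(flip, ifelse(action == "C", "D", "C"), action)
}

# Bush-Mosteller propensity update for one directed dyad.
# p: current propensity to cooperate; played: realized own action;
# payoff: realized own stage payoff; spec: the LEARNING strategy_spec.
bm_update <- function(p, played, payoff, spec, payoffs) {
  aspire <- payoffs$S + spec$aspiration * (payoffs$T - payoffs$S)
  denom <- max(payoffs$T - aspire, aspire - payoffs$S)
  if (denom <= 0) return(p)
  s <- (payoff - aspire) / denom  # stimulus in [-1, 1]
  if (played == "C") {
    p <- if (s >= 0) p + spec$rate * s * (1 - p) else p + spec$rate * s * p
  } else {
    p <- if (s >= 0) p - spec$rate * s * p else p - spec$rate * s * (1 - p)
  }
  min(max(p, 0), 1)
}
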