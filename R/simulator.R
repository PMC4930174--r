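#' Run one simulated group through the repeated game
#'
#' Agent-based play of the networked repeated Prisoner's Dilemma. Each
#' period: a fresh uniform m-regular matching is drawn; every matched actor
#' decides *simultaneously*, using only information accumulated through the
#' previous period; trembles (and any configured defection overlay) are
#' applied; stage payoffs are computed; and every actor's information state
#' is updated according to the group's information regime. Observations are
#' cumulative and never forgotten.
#'
#' Under `"atomized"` information an interaction's outcome is observed only
#' by its two participants (everyone still sees who was matched with whom);
#' under `"embedded"` information all outcomes are observed by everyone —
#' the reputation channel.
#'
#' @param config A [group_config()].
#' @param payoffs A [pd_payoffs()].
#' @param strategies A single [strategy_spec()] applied to every actor, or a
#'   list with one spec per actor.
#' @param seed Integer seed making the run fully reproducible; `NULL` uses
#'   the current RNG stream.
#' @param inject Optional forced defection, a list
#'   `list(period =, actor =, partner = NULL)`: in that period the actor's
#'   realized action in the dyad with `partner` (or, if `partner` is `NULL`
#'   or unmatched that period, in the actor's first matched dyad) is forced
#'   to `"D"`. A deliberate perturbation for studying retaliation cascades.
#' @param extra_defect_prob Optional numeric vector of length
#'   `config$periods`: per-period probability that a realized `"C"` is
#'   turned into a `"D"` (a one-way overlay used for endgame emulation; see
#'   [experiment_design()]).
#' @return A data frame of class `"rw_sim"` with one row per matched dyad
#'   and period: columns `period`, `actor_a`, `actor_b` (`actor_a <
#'   actor_b`), `intended_a`, `intended_b` (pre-tremble), `action_a`,
#'   `action_b` (realized), `payoff_a`, `payoff_b` (stage payoffs of the
#'   dyad). Attributes `n`, `m`, `condition`, `seed` describe the run.
#' @examples
#' cfg <- group_config(condition = "embedded")
#' rec <- run_group(cfg, strategies = strategy_spec("TRIGGER"), seed = 1)
#' cooperation_trajectory(rec)[1:5]  # all 1: no defection is ever observed
#' @export
run_group <- function(config, payoffs = pd_payoffs(),
                      strategies = strategy_spec("TRIGGER"), seed = NULL,
                      inject = NULL, extra_defect_prob = NULL) {
  stopifnot(inherits(config, "group_config"))
  payoffs <- as_pd_payoffs(payoffs)
  n <- config$n; m <- config$m; periods <- config$periods
  embedded <- config$condition == "embedded"
  if (inherits(strategies, "strategy_spec")) {
    strategies <- rep(list(strategies), n)
  }
  if (!is.list(strategies) || length(strategies) != n ||
      !all(vapply(strategies, inherits, logical(1L), "strategy_spec"))) {
    stop("`strategies` must be one strategy_spec or a list of n of them",
         call. = FALSE)
  }
  if (!is.null(extra_defect_prob) && length(extra_defect_prob) != periods) {
    stop("`extra_defect_prob` must have one entry per period", call. = FALSE)
  }

  k <- n * m / 2L  # dyads per period
  nrec <- k * periods
  col_period <- integer(nrec)
  col_a <- integer(nrec); col_b <- integer(nrec)
  col_ia <- character(nrec); col_ib <- character(nrec)
  col_ra <- character(nrec); col_rb <- character(nrec)
  col_pa <- numeric(nrec); col_pb <- numeric(nrec)

  with_seed(seed, {
    # seen[i, j]: actor i has observed actor j defect (within i's scope);
    # seen_uj additionally filters out retaliatory defections, for
    # discriminating triggers.
    seen <- matrix(FALSE, n, n)
    seen_uj <- matrix(FALSE, n, n)
    prop <- matrix(vapply(strategies, function(s) s$init, numeric(1L)),
                   n, n, byrow = FALSE)  # prop[i, j]: i's propensity to C with j

    for (t in seq_len(periods)) {
      mt <- sample_matching(n, m)
      a <- mt[, 1L]; b <- mt[, 2L]
      int_a <- character(k); int_b <- character(k)
      for (e in seq_len(k)) {
        sa <- strategies[[a[e]]]; sb <- strategies[[b[e]]]
        view_a <- if (sa$discriminating) seen_uj[a[e], ] else seen[a[e], ]
        view_b <- if (sb$discriminating) seen_uj[b[e], ] else seen[b[e], ]
        int_a[e] <- decide(a[e], b[e], sa,
                           list(seen_defect = view_a, propensity = prop[a[e], ]))
        int_b[e] <- decide(b[e], a[e], sb,
                           list(seen_defect = view_b, propensity = prop[b[e], ]))
      }
      tr_a <- vapply(strategies[a], function(s) s$tremble, numeric(1L))
      tr_b <- vapply(strategies[b], function(s) s$tremble, numeric(1L))
      real_a <- apply_tremble(int_a, tr_a)
      real_b <- apply_tremble(int_b, tr_b)
      if (!is.null(extra_defect_prob) && extra_defect_prob[t] > 0) {
        real_a <- ifelse(real_a == "C" &
                           stats::runif(k) < extra_defect_prob[t], "D", real_a)
        real_b <- ifelse(real_b == "C" &
                           stats::runif(k) < extra_defect_prob[t], "D", real_b)
      }
      if (!is.null(inject) && inject$period == t) {
        tgt <- which(a == inject$actor | b == inject$actor)
        if (!is.null(inject$partner)) {
          with_partner <- which((a == inject$actor & b == inject$partner) |
                                  (b == inject$actor & a == inject$partner))
          if (length(with_partner) > 0L) tgt <- with_partner
        }
        if (length(tgt) > 0L) {
          e <- tgt[1L]
          if (a[e] == inject$actor) real_a[e] <- "D" else real_b[e] <- "D"
        }
      }
      pay <- dyad_payoff(real_a, real_b, payoffs)

      idx <- (t - 1L) * k + seq_len(k)
      col_period[idx] <- t
      col_a[idx] <- a; col_b[idx] <- b
      col_ia[idx] <- int_a; col_ib[idx] <- int_b
      col_ra[idx] <- real_a; col_rb[idx] <- real_b
      col_pa[idx] <- pay[, "i"]; col_pb[idx] <- pay[, "j"]

      # information update, from a pre-period snapshot of `seen` so that
      # justification of retaliation is judged on prior knowledge
      seen_before <- seen
      for (e in seq_len(k)) {
        for (dir in 1:2) {
          p <- if (dir == 1L) a[e] else b[e]
          q <- if (dir == 1L) b[e] else a[e]
          act <- if (dir == 1L) real_a[e] else real_b[e]
          if (act == "D") {
            observers <- if (embedded) seq_len(n) else c(p, q)
            seen[observers, p] <- TRUE
            if (!seen_before[p, q]) seen_uj[observers, p] <- TRUE
          }
        }
      }
      for (e in seq_len(k)) {
        for (dir in 1:2) {
          p <- if (dir == 1L) a[e] else b[e]
          q <- if (dir == 1L) b[e] else a[e]
          sp <- strategies[[p]]
          if (sp$kind == "LEARNING") {
            act <- if (dir == 1L) real_a[e] else real_b[e]
            pf <- if (dir == 1L) pay[e, "i"] else pay[e, "j"]
            prop[p, q] <- bm_update(prop[p, q], act, pf, sp, payoffs)
          }
        }
      }
    }
  })

  structure(data.frame(period = col_period, actor_a = col_a, actor_b = col_b,
                       intended_a = col_ia, intended_b = col_ib,
                       action_a = col_ra, action_b = col_rb,
                       payoff_a = col_pa, payoff_b = col_pb,
                       stringsAsFactors = FALSE),
            class = c("rw_sim", "data.frame"),
            n = n, m = m, condition = config$condition, seed = seed)
}

#' Per-period cooperation proportions of a run
#'
#' For each period, the share of realized `"C"` actions among all `n * m`
#' actions played that period.
#'
#' @param records A simulation record data frame ([run_group()]) or any data
#'   frame with columns `period`, `action_a`, `action_b`.
#' @return Named numeric vector, one proportion per period (names are the
#'   period indices). The run's overall rate is `mean()` of it.
#' @examples
#' rec <- run_group(group_config(), strategies = strategy_spec("ALL_D"), seed = 1)
#' unique(cooperation_trajectory(rec))  # 0
#' @export
cooperation_trajectory <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("empty record set", call. = FALSE)
  }
  is_c <- c(records$action_a == "C", records$action_b == "C")
  per <- c(records$period, records$period)
  out <- tapply(is_c, factor(per, levels = sort(unique(per))), mean)
  stats::setNames(as.numeric(out), names(out))
}

#' @export
print.rw_sim <- function(x, ...) {
  cat(sprintf("Simulated group: n = %d, m = %d, %d periods, %s information\n",
              attr(x, "n"), attr(x, "m"), max(x$period), attr(x, "condition")))
  cat(sprintf("Overall cooperation rate: %.3f\n",
              mean(c(x$action_a, x$action_b) == "C")))
  NextMethod()
}
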