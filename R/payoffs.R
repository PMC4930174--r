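#' Stage-game and non-interaction payoffs
#'
#' Construct the payoff parameterization of the symmetric two-person
#' Prisoner's Dilemma plus the fixed payoff received for each potential
#' partner one is *not* matched with in a period. The defaults are the
#' laboratory parameterization used throughout the package: `T = 60`,
#' `R = 40`, `P = 20`, `S = 0` points per interaction and `Q = 30` points
#' per non-matched relation.
#'
#' @param T Temptation payoff (defect against a cooperator).
#' @param R Reward payoff (mutual cooperation).
#' @param P Punishment payoff (mutual defection).
#' @param S Sucker payoff (cooperate against a defector).
#' @param Q Non-interaction payoff, received once per potential partner not
#'   matched this period. `Q` never enters the equilibrium conditions; it is
#'   kept configurable.
#'
#' @return An object of class `"pd_payoffs"`: a named list with components
#'   `T`, `R`, `P`, `S`, `Q`.
#' @examples
#' pd_payoffs()
#' pd_payoffs(T = 5, R = 3, P = 1, S = 0, Q = 0)
#' @export
pd_payoffs <- function(T = 60, R = 40, P = 20, S = 0, Q = 30) {
  vals <- c(T = T, R = R, P = P, S = S, Q = Q)
  if (!is.numeric(vals) || length(vals) != 5L || any(!is.finite(vals))) {
    stop("all payoffs must be finite numbers", call. = FALSE)
  }
  if (!(T > R && R > P && P > S)) {
    stop("payoffs must satisfy the Prisoner's Dilemma ordering T > R > P > S",
         call. = FALSE)
  }
  structure(list(T = T, R = R, P = P, S = S, Q = Q), class = "pd_payoffs")
}

#' @export
print.pd_payoffs <- function(x, ...) {
  cat("Prisoner's Dilemma payoffs (points):\n")
  cat(sprintf("  T = %g, R = %g, P = %g, S = %g; non-interaction Q = %g\n",
              x$T, x$R, x$P, x$S, x$Q))
  invisible(x)
}

as_pd_payoffs <- function(x) {
  if (inherits(x, "pd_payoffs")) return(x)
  if (is.list(x) || is.numeric(x)) {
    x <- as.list(x)
    return(do.call(pd_payoffs, x[intersect(names(x), c("T", "R", "P", "S", "Q"))]))
  }
  stop("cannot interpret `payoffs`", call. = FALSE)
}

#' Group-level game configuration
#'
#' @param n Number of actors in the (complete) network.
#' @param m Number of interaction partners each actor is matched with per
#'   period. Requires `1 <= m <= n - 1` and `n * m` even, so that an
#'   m-regular interaction graph exists.
#' @param periods Number of scored periods.
#' @param condition Information regime: `"atomized"` (actors observe only
#'   the outcomes of their own interactions, though they see who was matched
#'   with whom) or `"embedded"` (actors observe the outcomes of all
#'   interactions in the group).
#'
#' @return An object of class `"group_config"`.
#' @examples
#' group_config()                     # the lab defaults: n = 6, m = 2, 40 periods
#' group_config(condition = "embedded")
#' @export
group_config <- function(n = 6, m = 2, periods = 40,
                         condition = c("atomized", "embedded")) {
  condition <- match.arg(condition)
  check_n_m(n, m)
  if (!is.numeric(periods) || length(periods) != 1L || periods < 1 ||
      periods != round(periods)) {
    stop("`periods` must be a positive integer", call. = FALSE)
  }
  structure(list(n = as.integer(n), m = as.integer(m),
                 periods = as.integer(periods), condition = condition),
            class = "group_config")
}

#' @export
print.group_config <- function(x, ...) {
  cat(sprintf("Group: n = %d actors, m = %d partners/period, %d periods, %s information\n",
              x$n, x$m, x$periods, x$condition))
  invisible(x)
}

check_n_m <- function(n, m) {
  if (!is.numeric(n) || !is.numeric(m) || length(n) != 1L || length(m) != 1L ||
      n != round(n) || m != round(m)) {
    stop("`n` and `m` must be integers", call. = FALSE)
  }
  if (m < 1 || m > n - 1) {
    stop(sprintf("need 1 <= m <= n - 1 (got n = %d, m = %d)", n, m),
         call. = FALSE)
  }
  if ((n * m) %% 2 != 0) {
    stop(sprintf("no m-regular graph exists: n * m = %d is odd", n * m),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Payoffs of one matched dyad
#'
#' Stage-game payoffs for a matched pair given both actions. Vectorized over
#' pairs of actions.
#'
#' @param action_i,action_j Actions `"C"` (cooperate) or `"D"` (defect);
#'   the lab labels `"ORANGE"`/`"BLUE"` are accepted as aliases.
#' @param payoffs A [pd_payoffs()] object.
#' @return A two-column numeric matrix with columns `i` and `j`, one row per
#'   dyad.
#' @examples
#' dyad_payoff("C", "C")  # (40, 40)
#' dyad_payoff("D", "C")  # (60, 0)
#' @export
dyad_payoff <- function(action_i, action_j, payoffs = pd_payoffs()) {
  payoffs <- as_pd_payoffs(payoffs)
  ai <- normalize_actions(action_i)
  aj <- normalize_actions(action_j)
  if (length(ai) != length(aj)) stop("action vectors must match in length", call. = FALSE)
  # own payoff indexed by (own, other): CC->R, CD->S, DC->T, DD->P
  pay <- function(own, other) {
    ifelse(own == "C",
           ifelse(other == "C", payoffs$R, payoffs$S),
           ifelse(other == "C", payoffs$T, payoffs$P))
  }
  cbind(i = pay(ai, aj), j = pay(aj, ai))
}

#' Total points of one actor in one period
#'
#' Sum of the actor's `m` stage-game payoffs plus the fixed
#' `(n - 1 - m) * Q` baseline for the potential partners the actor was not
#' matched with. With the default parameterization the baseline is
#' `3 * 30 = 90` points per period.
#'
#' @param actor Actor index in `1..n`.
#' @param matching A matching as returned by [sample_matching()]: a
#'   two-column integer matrix of dyads.
#' @param actions A data frame (or list) with elements `action_a` and
#'   `action_b` aligned row-wise with `matching`, giving the action of the
#'   first and second actor of each dyad.
#' @param payoffs A [pd_payoffs()] object.
#' @param config A [group_config()] object.
#' @return Total points (scalar).
#' @examples
#' cfg <- group_config()
#' mt <- rbind(c(1, 2), c(1, 3), c(2, 4), c(3, 5), c(4, 6), c(5, 6))
#' acts <- data.frame(action_a = c("C", "D", "C", "C", "C", "C"),
#'                    action_b = rep("C", 6))
#' period_payoff(1, mt, acts)  # R + T + 3Q = 40 + 60 + 90 = 190
#' @export
period_payoff <- function(actor, matching, actions, payoffs = pd_payoffs(),
                          config = group_config()) {
  payoffs <- as_pd_payoffs(payoffs)
  n <- config$n; m <- config$m
  if (!(actor %in% seq_len(n))) {
    stop(sprintf("actor index %s out of range 1..%d", actor, n), call. = FALSE)
  }
  matching <- as.matrix(matching)
  rows <- which(matching[, 1L] == actor | matching[, 2L] == actor)
  if (length(rows) != m) {
    stop(sprintf("actor %d appears in %d dyads, expected m = %d",
                 actor, length(rows), m), call. = FALSE)
  }
  aa <- normalize_actions(actions$action_a)
  ab <- normalize_actions(actions$action_b)
  if (length(aa) != nrow(matching) || length(ab) != nrow(matching) ||
      anyNA(aa[rows]) || anyNA(ab[rows])) {
    stop("missing action for a matched dyad", call. = FALSE)
  }
  own   <- ifelse(matching[rows, 1L] == actor, aa[rows], ab[rows])
  other <- ifelse(matching[rows, 1L] == actor, ab[rows], aa[rows])
  sum(dyad_payoff(own, other, payoffs)[, "i"]) + (n - 1 - m) * payoffs$Q
}

#' Per-period probability that a given relation is matched
#'
#' In an n-actor group where each actor is matched with exactly m partners
#' per period, each of the `n(n-1)/2` dyads is used with probability
#' `pi = m / (n - 1)`.
#'
#' @inheritParams group_config
#' @return The probability `m / (n - 1)`.
#' @examples
#' interaction_probability(6, 2)  # 0.4
#' @export
interaction_probability <- function(n, m) {
  if (m < 1 || m > n - 1) stop("need 1 <= m <= n - 1", call. = FALSE)
  m / (n - 1)
}

# Map lab labels onto canonical actions; NA and unknown labels are an error.
normalize_actions <- function(a) {
  a <- toupper(as.character(a))
  out <- ifelse(a %in% c("C", "ORANGE"), "C",
                ifelse(a %in% c("D", "BLUE"), "D", NA_character_))
  if (anyNA(out)) {
    bad <- unique(a[is.na(out)])
    stop(sprintf("unknown action label(s): %s (expected C/D or ORANGE/BLUE)",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  out
}
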