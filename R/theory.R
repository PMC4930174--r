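# Closed-form expected utilities and threshold discount factors for
# conditional cooperation under the two information regimes.
#
# An actor discounts future payoffs with factor beta (equivalently, the game
# continues each period with probability beta). Against opponents playing the
# trigger strategy, the candidate deviation is ALL-D; conditional cooperation
# is an equilibrium iff EU(ALL-C) >= EU(ALL-D), which holds iff beta exceeds a
# threshold that depends on the information regime.

check_beta <- function(beta) {
  if (!is.numeric(beta) || any(beta <= 0) || any(beta >= 1)) {
    stop("`beta` must lie strictly inside (0, 1)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Discounted expected utility of unconditional cooperation
#'
#' Expected present value for an actor playing ALL-C while all others play
#' the trigger strategy: every period yields `m R` from matched partners plus
#' `(n - 1 - m) Q` from unmatched relations, so the total is
#' `(m R + (n - 1 - m) Q) / (1 - beta)`. Identical in the two information
#' regimes.
#'
#' @param payoffs A [pd_payoffs()] object.
#' @inheritParams group_config
#' @param beta Discount factor in (0, 1); vectorized.
#' @return Discounted points.
#' @examples
#' eu_all_c(beta = 0.5)    # 340
#' eu_all_c(beta = 5 / 7)  # 595
#' @export
eu_all_c <- function(payoffs = pd_payoffs(), n = 6, m = 2, beta) {
  payoffs <- as_pd_payoffs(payoffs)
  check_n_m(n, m); check_beta(beta)
  (m * payoffs$R + (n - 1 - m) * payoffs$Q) / (1 - beta)
}

#' Discounted expected utility of defection under embedded information
#'
#' Under embedded information the deviator earns `T` from each of its `m`
#' first-period partners, but from period 2 on every actor is informed and
#' defects, leaving `P` in every matched interaction:
#' `m T + beta m P / (1 - beta) + (n - 1 - m) Q / (1 - beta)`.
#'
#' @inheritParams eu_all_c
#' @return Discounted points.
#' @examples
#' eu_all_d_embedded(beta = 0.5)  # 340: indifferent with ALL-C at beta_emb
#' eu_all_d_embedded(beta = 0.9)  # 1380
#' @export
eu_all_d_embedded <- function(payoffs = pd_payoffs(), n = 6, m = 2, beta) {
  payoffs <- as_pd_payoffs(payoffs)
  check_n_m(n, m); check_beta(beta)
  m * payoffs$T + beta * m * payoffs$P / (1 - beta) +
    (n - 1 - m) * payoffs$Q / (1 - beta)
}

#' Discounted expected utility of defection under atomized information
#'
#' Under atomized information each of the `n - 1` relations learns of the
#' deviation only through its own interactions. With
#' `pi = m / (n - 1)` the per-period matching probability of a relation, a
#' relation pays `T` the first time it is matched and `P` on subsequent
#' matches, giving
#' `m P / (1 - beta) + m (T - P) / (1 - beta (1 - pi)) + (n - 1 - m) Q / (1 - beta)`.
#'
#' @inheritParams eu_all_c
#' @return Discounted points.
#' @examples
#' eu_all_d_atomized(beta = 5 / 7)  # 595: indifferent with ALL-C at beta_ato
#' eu_all_d_atomized(beta = 0.5)    # ~374.2857
#' @export
eu_all_d_atomized <- function(payoffs = pd_payoffs(), n = 6, m = 2, beta) {
  payoffs <- as_pd_payoffs(payoffs)
  check_n_m(n, m); check_beta(beta)
  pi <- m / (n - 1)
  m * payoffs$P / (1 - beta) +
    m * (payoffs$T - payoffs$P) / (1 - beta * (1 - pi)) +
    (n - 1 - m) * payoffs$Q / (1 - beta)
}

#' Threshold discount factor, embedded information
#'
#' The minimal discount factor sustaining conditional cooperation when
#' information about defections reaches all actors immediately:
#' `beta_emb = (T - R) / (T - P)` — the classic dyadic repeated-game
#' condition, independent of `Q`, `n` and `m`.
#'
#' @inheritParams eu_all_c
#' @return Threshold in (0, 1).
#' @examples
#' beta_threshold_embedded()  # 0.5
#' @export
beta_threshold_embedded <- function(payoffs = pd_payoffs()) {
  payoffs <- as_pd_payoffs(payoffs)
  (payoffs$T - payoffs$R) / (payoffs$T - payoffs$P)
}

#' Threshold discount factor, atomized information
#'
#' The minimal discount factor sustaining conditional cooperation when
#' defections are observed only within one's own interactions:
#' `beta_ato = (T - R) / (T - P - (R - P)(1 - pi))` with
#' `pi = m / (n - 1)`. Always at least [beta_threshold_embedded()], with
#' equality exactly when `m = n - 1` (everyone interacts every period).
#' Independent of `Q`.
#'
#' @inheritParams eu_all_c
#' @return Threshold in (0, 1).
#' @examples
#' beta_threshold_atomized()  # 5/7
#' @export
beta_threshold_atomized <- function(payoffs = pd_payoffs(), n = 6, m = 2) {
  payoffs <- as_pd_payoffs(payoffs)
  check_n_m(n, m)
  pi <- m / (n - 1)
  (payoffs$T - payoffs$R) /
    (payoffs$T - payoffs$P - (payoffs$R - payoffs$P) * (1 - pi))
}

#' Signed expected-utility gap between cooperation and defection
#'
#' `eu_all_c - eu_all_d_<condition>` at a stated discount factor. Positive
#' exactly when `beta` exceeds the corresponding threshold; zero at the
#' threshold.
#'
#' @inheritParams eu_all_c
#' @param condition `"embedded"` or `"atomized"`.
#' @return Signed gap in discounted points (vectorized over `beta`).
#' @examples
#' indifference_check(beta = 0.5, condition = "embedded")    # 0
#' indifference_check(beta = 5 / 7, condition = "atomized")  # 0
#' indifference_check(beta = 0.6, condition = "embedded")    # > 0
#' @export
indifference_check <- function(payoffs = pd_payoffs(), n = 6, m = 2, beta,
                               condition = c("embedded", "atomized")) {
  condition <- match.arg(condition)
  eu_d <- switch(condition,
                 embedded = eu_all_d_embedded(payoffs, n, m, beta),
                 atomized = eu_all_d_atomized(payoffs, n, m, beta))
  eu_all_c(payoffs, n, m, beta) - eu_d
}

#' Finite-horizon expected utilities (diagnostic)
#'
#' Truncated-sum evaluation of the expected utilities over a finite horizon
#' of `horizon` periods. This is a diagnostic for comparing the
#' infinite-horizon theory with the 40-period laboratory game; it is *not* an
#' equilibrium analysis of the finite game (the finitely repeated game has a
#' different equilibrium structure).
#'
#' @inheritParams eu_all_c
#' @param horizon Number of periods summed.
#' @return A named numeric vector with components `all_c`,
#'   `all_d_embedded`, `all_d_atomized`.
#' @examples
#' eu_finite_horizon(beta = 0.5, horizon = 40)
#' @export
eu_finite_horizon <- function(payoffs = pd_payoffs(), n = 6, m = 2, beta,
                              horizon = 40) {
  payoffs <- as_pd_payoffs(payoffs)
  check_n_m(n, m); check_beta(beta)
  stopifnot(horizon >= 1)
  t <- seq_len(horizon)
  disc <- beta^(t - 1)
  pi <- m / (n - 1)
  base <- (n - 1 - m) * payoffs$Q
  all_c <- sum(disc * (m * payoffs$R + base))
  all_d_emb <- m * payoffs$T + base +
    sum(disc[-1] * (m * payoffs$P + base))
  # per-relation three-case expectation, summed over n - 1 relations
  per_rel <- pi * (1 - pi)^(t - 1) * payoffs$T +
    pi * (1 - (1 - pi)^(t - 1)) * payoffs$P +
    (1 - pi) * payoffs$Q
  all_d_ato <- (n - 1) * sum(disc * per_rel)
  c(all_c = all_c, all_d_embedded = all_d_emb, all_d_atomized = all_d_ato)
}
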