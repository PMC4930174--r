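# Group-level cooperation summaries and the hypothesis-testing pipeline.
# The group is the unit of analysis throughout: tests compare per-group
# cooperation rates between the two information conditions.

#' Cooperation rate of one group over a period window
#'
#' Share of `"C"` actions among all actions played by the group's members in
#' the window. The default window 1-35 excludes the final five periods of a
#' 40-period game, where endgame effects distort behavior.
#'
#' @param dataset An experiment dataset (see [generate_experiment()]).
#' @param group Group id present in the dataset.
#' @param period_lo,period_hi Inclusive period window.
#' @return Proportion in `[0, 1]`.
#' @export
group_cooperation_rate <- function(dataset, group, period_lo = 1,
                                   period_hi = 35) {
  dg <- dataset[dataset$group == group &
                  dataset$period >= period_lo & dataset$period <= period_hi, ]
  if (nrow(dg) == 0L) {
    stop(sprintf("no records for group %s in periods %d-%d",
                 group, period_lo, period_hi), call. = FALSE)
  }
  mean(c(dg$action_a, dg$action_b) == "C")
}

#' First-interaction cooperation rate of one group
#'
#' For each dyad of the group, take the first period in which the pair was
#' matched; the rate is the share of `"C"` among the actions played in those
#' first encounters. Dyads that never match are excluded from the
#' denominator.
#'
#' @inheritParams group_cooperation_rate
#' @param level `"action"` (default): each of the two first-encounter
#'   actions counts separately; `"dyad"`: a first encounter counts as one
#'   observation, cooperative only if *both* actors played `"C"`.
#' @return Proportion in `[0, 1]`.
#' @export
first_interaction_cooperation <- function(dataset, group,
                                          level = c("action", "dyad")) {
  level <- match.arg(level)
  dg <- dataset[dataset$group == group, ]
  if (nrow(dg) == 0L) stop(sprintf("group %s not found", group), call. = FALSE)
  key <- paste(pmin(dg$actor_a, dg$actor_b), pmax(dg$actor_a, dg$actor_b))
  first <- dg[order(dg$period), ]
  first <- first[!duplicated(paste(pmin(first$actor_a, first$actor_b),
                                   pmax(first$actor_a, first$actor_b))), ]
  if (level == "action") {
    mean(c(first$action_a, first$action_b) == "C")
  } else {
    mean(first$action_a == "C" & first$action_b == "C")
  }
}

# Per-group summary table feeding the tests.
group_stats <- function(dataset, main_window = c(1, 35),
                        end_window = c(30, 35), first_level = "action") {
  groups <- unique(dataset[, c("experiment", "group", "condition")])
  groups$coop_rate_main <- vapply(groups$group, function(g) {
    group_cooperation_rate(dataset, g, main_window[1L], main_window[2L])
  }, numeric(1L))
  groups$coop_rate_first <- vapply(groups$group, function(g) {
    first_interaction_cooperation(dataset, g, level = first_level)
  }, numeric(1L))
  groups$coop_rate_endwindow <- vapply(groups$group, function(g) {
    group_cooperation_rate(dataset, g, end_window[1L], end_window[2L])
  }, numeric(1L))
  rownames(groups) <- NULL
  groups
}

new_rw_test <- function(statistic, p_value, n_a, n_b, alternative, method,
                        degenerate = FALSE, note = NULL) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 n_a = n_a, n_b = n_b, alternative = alternative,
                 method = method, degenerate = degenerate, note = note),
            class = "rw_test")
}

#' @export
print.rw_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s; n = %d vs %d)%s\n",
              x$method, x$statistic, x$p_value, x$alternative, x$n_a, x$n_b,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Mann-Whitney U test on group-level rates
#'
#' Rank-based comparison of two independent samples of per-group
#' proportions. For combined sample sizes `N <= 20` the p-value is exact,
#' from full enumeration of all `choose(N, n_a)` assignments of the midranks
#' to the first sample; above that a normal approximation with tie
#' correction (and continuity correction) is used.
#'
#' `alternative = "greater"` means the first sample tends to take larger
#' values.
#'
#' @param rates_a,rates_b Numeric vectors (one value per group).
#' @param alternative `"two.sided"`, `"greater"`, or `"less"`.
#' @param exact Force (`TRUE`) or suppress (`FALSE`) enumeration; default
#'   enumerates when `N <= 20`.
#' @return An object of class `"rw_test"` carrying the U statistic (for the
#'   first sample) and the p-value.
#' @examples
#' mann_whitney(c(0.9, 0.8, 0.7), c(0.2, 0.3, 0.4), alternative = "greater")
#' # complete separation of 3 vs 3: exact p = 1/20
#' @export
mann_whitney <- function(rates_a, rates_b,
                         alternative = c("two.sided", "greater", "less"),
                         exact = NULL) {
  alternative <- match.arg(alternative)
  na <- length(rates_a); nb <- length(rates_b)
  if (na < 1L || nb < 1L) stop("both arms must be non-empty", call. = FALSE)
  N <- na + nb
  if (is.null(exact)) exact <- N <= 20L
  r <- rank(c(rates_a, rates_b))  # midranks
  w_obs <- sum(r[seq_len(na)])
  u_obs <- w_obs - na * (na + 1) / 2
  if (exact) {
    splits <- utils::combn(N, na)
    w_all <- colSums(matrix(r[splits], nrow = na))
    p_ge <- mean(w_all >= w_obs - 1e-9)
    p_le <- mean(w_all <= w_obs + 1e-9)
    p <- switch(alternative,
                greater = p_ge,
                less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    method <- "Exact Mann-Whitney U test (permutation enumeration)"
  } else {
    mu <- na * nb / 2
    ties <- table(r)
    sigma2 <- na * nb / 12 * (N + 1 - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      return(new_rw_test(u_obs, 1, na, nb, alternative,
                         "Mann-Whitney U test (normal approximation)",
                         degenerate = TRUE, note = "all observations tied"))
    }
    z <- function(u, shift) (u - mu + shift) / sqrt(sigma2)
    p <- switch(alternative,
                greater = stats::pnorm(z(u_obs, -0.5), lower.tail = FALSE),
                less = stats::pnorm(z(u_obs, 0.5)),
                two.sided = min(1, 2 * min(
                  stats::pnorm(z(u_obs, -0.5), lower.tail = FALSE),
                  stats::pnorm(z(u_obs, 0.5)))))
    method <- "Mann-Whitney U test (normal approximation, tie-corrected)"
  }
  degen <- length(unique(c(rates_a, rates_b))) == 1L
  new_rw_test(u_obs, p, na, nb, alternative, method, degenerate = degen,
              note = if (degen) "all observations tied" else NULL)
}

#' Variance-comparison test on group-level rates
#'
#' Tests whether dispersion across groups differs between conditions. The
#' default is the F test on the ratio of unbiased sample variances
#' `s2_a / s2_b` (via [stats::var.test()]); a label-permutation alternative
#' using the same ratio statistic guards against non-normality.
#'
#' `alternative = "greater"` means the first sample has the larger variance.
#'
#' @inheritParams mann_whitney
#' @param method `"F"` or `"permutation"`.
#' @param n_perm Number of permutations for `method = "permutation"`.
#' @param seed Seed for the permutation draw.
#' @return An object of class `"rw_test"` carrying the variance ratio.
#' @export
variance_comparison <- function(rates_a, rates_b,
                                alternative = c("greater", "less", "two.sided"),
                                method = c("F", "permutation"),
                                n_perm = 10000, seed = 1) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  na <- length(rates_a); nb <- length(rates_b)
  if (na < 2L || nb < 2L) stop("need >= 2 groups per arm", call. = FALSE)
  va <- stats::var(rates_a); vb <- stats::var(rates_b)
  if (vb == 0 && va == 0) {
    stop("degenerate variance comparison: both arms have zero variance",
         call. = FALSE)
  }
  if (vb == 0 || va == 0) {
    stop("degenerate variance comparison: an arm has zero variance",
         call. = FALSE)
  }
  if (method == "F") {
    vt <- stats::var.test(rates_a, rates_b, alternative = alternative)
    new_rw_test(unname(vt$statistic), vt$p.value, na, nb, alternative,
                "F test of variance ratio")
  } else {
    ratio_obs <- va / vb
    pool <- c(rates_a, rates_b)
    ratios <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(na + nb, na)
        stats::var(pool[idx]) / stats::var(pool[-idx])
      }, numeric(1L))
    })
    p_ge <- (1 + sum(ratios >= ratio_obs - 1e-12)) / (1 + n_perm)
    p_le <- (1 + sum(ratios <= ratio_obs + 1e-12)) / (1 + n_perm)
    p <- switch(alternative,
                greater = p_ge, less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    new_rw_test(ratio_obs, p, na, nb, alternative,
                sprintf("Permutation variance-ratio test (%d permutations)", n_perm))
  }
}

#' Power of the two-sample t-test for a difference in cooperation rates
#'
#' Exact noncentral-t power of the two-sample t-test for detecting a mean
#' difference `delta` between two conditions with common per-group standard
#' deviation `sd` and `n` groups per condition (noncentrality
#' `delta / sd * sqrt(n / 2)`, `2n - 2` degrees of freedom). Wraps
#' [stats::power.t.test()].
#'
#' @param delta Mean difference, in proportion units (`>= 0`).
#' @param sd Per-group standard deviation (`> 0`).
#' @param n Groups per condition (`>= 2`).
#' @param alpha Significance level.
#' @param alternative `"one.sided"` (default: the hypothesis is directional)
#'   or `"two.sided"`.
#' @return Power, a probability.
#' @examples
#' t_test_power(delta = 0.19, sd = 0.1, n = 5)  # > 0.80
#' @export
t_test_power <- function(delta, sd, n, alpha = 0.05,
                         alternative = c("one.sided", "two.sided")) {
  alternative <- match.arg(alternative)
  if (!is.numeric(delta) || delta < 0) stop("`delta` must be >= 0", call. = FALSE)
  if (!is.numeric(sd) || sd <= 0) stop("`sd` must be > 0", call. = FALSE)
  if (!is.numeric(n) || n < 2) stop("`n` must be >= 2", call. = FALSE)
  if (delta == 0) {
    return(alpha)  # size of the test under the null
  }
  stats::power.t.test(n = n, delta = delta, sd = sd, sig.level = alpha,
                      type = "two.sample", alternative = alternative)$power
}

#' Run the full hypothesis-testing pipeline on a dataset
#'
#' Per experiment and pooled across experiments, the report contains:
#'
#' * H1: Mann-Whitney test of the main-window (default periods 1-35)
#'   per-group cooperation rates, embedded vs atomized;
#' * H2: the same test on first-interaction cooperation rates;
#' * an endgame-window table (default periods 30-35): mean and SD of group
#'   cooperation per condition, with a variance-comparison test of whether
#'   dispersion is larger under embedded information.
#'
#' P-values are reported raw; no multiplicity adjustment is applied. Tests
#' on degenerate inputs (e.g. an all-cooperation dataset, where every rate
#' is 1) are flagged rather than failed.
#'
#' @param dataset An experiment dataset; validated before analysis.
#' @param alternative Sidedness of the H1/H2 Mann-Whitney tests (default
#'   two-sided). `"greater"` means embedded larger.
#' @param alpha Nominal significance level echoed into the report.
#' @param main_window,end_window Inclusive period windows.
#' @param first_level Passed to [first_interaction_cooperation()].
#' @param var_method Passed to [variance_comparison()].
#' @return An object of class `"rw_report"`: a nested list that serializes
#'   to stable JSON via [report_json()].
#' @examples
#' d <- generate_experiment(experiment_design("exp2",
#'   mixture = strategy_mixture(TRIGGER = 1, tremble = 0.05), seed = 1))
#' rep <- run_hypothesis_suite(d)
#' rep$pooled$h1$p_value
#' @export
run_hypothesis_suite <- function(dataset,
                                 alternative = c("two.sided", "greater", "less"),
                                 alpha = 0.05,
                                 main_window = c(1, 35), end_window = c(30, 35),
                                 first_level = c("action", "dyad"),
                                 var_method = c("F", "permutation")) {
  alternative <- match.arg(alternative)
  first_level <- match.arg(first_level)
  var_method <- match.arg(var_method)
  validate_dataset(dataset)
  gs <- group_stats(dataset, main_window, end_window, first_level)
  if (length(setdiff(c("atomized", "embedded"), unique(gs$condition))) > 0L) {
    stop("dataset must contain both an atomized and an embedded arm",
         call. = FALSE)
  }
  analyze_block <- function(gsub) {
    emb <- gsub[gsub$condition == "embedded", ]
    ato <- gsub[gsub$condition == "atomized", ]
    h1 <- mann_whitney(emb$coop_rate_main, ato$coop_rate_main, alternative)
    h2 <- mann_whitney(emb$coop_rate_first, ato$coop_rate_first, alternative)
    var_test <- tryCatch(
      variance_comparison(emb$coop_rate_endwindow, ato$coop_rate_endwindow,
                          alternative = "greater", method = var_method),
      error = function(e) new_rw_test(NA_real_, NA_real_, nrow(emb), nrow(ato),
                                      "greater", "F test of variance ratio",
                                      degenerate = TRUE, note = conditionMessage(e)))
    list(n_embedded = nrow(emb), n_atomized = nrow(ato),
         h1 = h1, h2 = h2,
         end_window = list(
           mean_embedded = mean(emb$coop_rate_endwindow),
           sd_embedded = stats::sd(emb$coop_rate_endwindow),
           mean_atomized = mean(ato$coop_rate_endwindow),
           sd_atomized = stats::sd(ato$coop_rate_endwindow),
           variance_test = var_test))
  }
  experiments <- lapply(split(gs, gs$experiment), analyze_block)
  structure(list(options = list(alternative = alternative, alpha = alpha,
                                main_window = main_window,
                                end_window = end_window,
                                first_level = first_level,
                                var_method = var_method,
                                note = paste("Mann-Whitney tests are",
                                             alternative, "; power analyses",
                                             "are one-sided by default",
                                             "(directional hypothesis)")),
                 group_stats = gs,
                 experiments = experiments,
                 pooled = analyze_block(gs)),
            class = "rw_report")
}

#' Serialize a hypothesis report to JSON
#'
#' Byte-stable serialization: rerunning the suite on the same dataset and
#' serializing again yields an identical string.
#'
#' @param report An `"rw_report"` from [run_hypothesis_suite()].
#' @param path Optional file to write to.
#' @return The JSON string, invisibly if `path` is given.
#' @export
report_json <- function(report, path = NULL) {
  json <- jsonlite::toJSON(unclass_deep(report), auto_unbox = TRUE,
                           digits = NA, null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

unclass_deep <- function(x) {
  if (is.data.frame(x)) {
    class(x) <- "data.frame"
    return(x)
  }
  if (is.list(x)) {
    x <- lapply(x, unclass_deep)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' @export
print.rw_report <- function(x, ...) {
  cat("Hypothesis report (unit of analysis: the group)\n")
  show_block <- function(b, label) {
    cat(sprintf("\n== %s (embedded n = %d, atomized n = %d) ==\n",
                label, b$n_embedded, b$n_atomized))
    cat("H1 main-window cooperation, embedded vs atomized:\n  "); print(b$h1)
    cat("H2 first-interaction cooperation, embedded vs atomized:\n  "); print(b$h2)
    cat(sprintf("End-window mean (SD): embedded %.3f (%.3f), atomized %.3f (%.3f)\n",
                b$end_window$mean_embedded, b$end_window$sd_embedded,
                b$end_window$mean_atomized, b$end_window$sd_atomized))
    cat("Variance comparison (embedded more dispersed):\n  ")
    print(b$end_window$variance_test)
  }
  for (nm in names(x$experiments)) show_block(x$experiments[[nm]], nm)
  if (length(x$experiments) > 1L) show_block(x$pooled, "pooled")
  invisible(x)
}

#' Generate-and-analyze convenience wrapper
#'
#' Chains [generate_experiment()] and [run_hypothesis_suite()] for a preset
#' design.
#'
#' @param preset `"exp1"` or `"exp2"`.
#' @param seed Top-level seed.
#' @param mixture A [strategy_mixture()].
#' @param endgame_max See [experiment_design()].
#' @param ... Passed to [run_hypothesis_suite()].
#' @return A list with components `dataset` and `report`.
#' @export
replicate_experiment <- function(preset = c("exp1", "exp2"), seed = 1,
                                 mixture = strategy_mixture(TRIGGER = 1,
                                                            tremble = 0.05),
                                 endgame_max = 0.3, ...) {
  preset <- match.arg(preset)
  design <- experiment_design(preset, mixture = mixture,
                              endgame_max = endgame_max, seed = seed)
  dataset <- generate_experiment(design)
  list(dataset = dataset, report = run_hypothesis_suite(dataset, ...))
}
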