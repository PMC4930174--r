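# Generator of lab-shaped datasets: complete multi-group experiments in the
# flat one-row-per-dyad-period format the analysis stage consumes.

dataset_columns <- c("experiment", "group", "condition", "period",
                     "actor_a", "actor_b", "action_a", "action_b",
                     "payoff_a", "payoff_b")

#' Mixture distribution over strategies
#'
#' A distribution from which each simulated actor's strategy is drawn
#' independently.
#'
#' @param ... Named weights over default-parameterized strategy kinds, e.g.
#'   `strategy_mixture(TRIGGER = 0.5, ALL_D = 0.5)`. Ignored when `specs`
#'   is supplied.
#' @param specs Optional list of [strategy_spec()] objects, for mixtures
#'   over non-default parameterizations.
#' @param weights Probabilities aligned with `specs`; must sum to 1.
#' @param tremble Tremble applied to every kind named in `...` (ignored with
#'   `specs`).
#' @return An object of class `"strategy_mixture"`: a list with `specs` and
#'   `weights`.
#' @examples
#' strategy_mixture(TRIGGER = 1, tremble = 0.02)
#' strategy_mixture(specs = list(strategy_spec("ALL_C"),
#'                               strategy_spec("TRIGGER", tremble = 0.05)),
#'                  weights = c(0.3, 0.7))
#' @export
strategy_mixture <- function(..., specs = NULL, weights = NULL, tremble = 0) {
  if (is.null(specs)) {
    w <- c(...)
    if (length(w) == 0L) stop("empty mixture", call. = FALSE)
    if (is.null(names(w)) || any(names(w) == "")) {
      stop("mixture weights must be named by strategy kind", call. = FALSE)
    }
    specs <- lapply(names(w), strategy_spec, tremble = tremble)
    weights <- unname(w)
  }
  if (!is.list(specs) ||
      !all(vapply(specs, inherits, logical(1L), "strategy_spec"))) {
    stop("`specs` must be a list of strategy_spec objects", call. = FALSE)
  }
  if (length(weights) != length(specs) || any(weights < 0)) {
    stop("`weights` must be nonnegative and aligned with `specs`", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-8) {
    stop("mixture weights must sum to 1", call. = FALSE)
  }
  structure(list(specs = specs, weights = weights), class = "strategy_mixture")
}

#' @export
print.strategy_mixture <- function(x, ...) {
  cat("Strategy mixture:\n")
  for (i in seq_along(x$specs)) {
    cat(sprintf("  %4.0f%%  ", 100 * x$weights[i])); print(x$specs[[i]])
  }
  invisible(x)
}

#' Design of a synthetic multi-group experiment
#'
#' Describes a complete experiment: how many groups per information
#' condition, the group configuration, the strategy mixture actors are drawn
#' from, and an optional endgame-defection ramp. Two presets mirror the
#' standard designs: `"exp1"` (7 atomized + 7 embedded groups) and `"exp2"`
#' (6 + 6); both use 6-person groups, 2 partners per period, 40 periods.
#'
#' The endgame ramp emulates the human tendency to defect in the closing
#' rounds of a finitely repeated game: an extra one-way probability of a
#' realized cooperation turning into defection, rising linearly from 0 at
#' period `periods - 4` to `endgame_max` at the final period. It is a
#' labeled pipeline-testing device emulating a robust feature of human play,
#' not a behavioral model; it is on by default (`endgame_max = 0.3`) because
#' the generated data stand in for lab data, and should be disabled
#' (`endgame_max = 0`) when emulating the theory's noise-free world. The
#' default analysis window (periods 1-35) is unaffected by it either way.
#'
#' @param preset `"exp1"`, `"exp2"`, or `"custom"`.
#' @param groups_per_condition Number of groups in each of the two
#'   conditions (required for `"custom"`, fixed by the presets otherwise).
#' @param config A [group_config()]; its `condition` field is overridden per
#'   group. Defaults to the standard 6-actor, 2-partner, 40-period group.
#' @param mixture A [strategy_mixture()].
#' @param endgame_max Maximum extra defection probability reached at the
#'   final period (0 disables the ramp; the device covers only the last 5
#'   periods).
#' @param seed Top-level integer seed; each group receives a seed derived
#'   from it and the group's position, so adding groups does not perturb
#'   existing ones.
#' @return An object of class `"experiment_design"`.
#' @examples
#' experiment_design("exp1", mixture = strategy_mixture(TRIGGER = 1), seed = 1)
#' @export
experiment_design <- function(preset = c("exp1", "exp2", "custom"),
                              groups_per_condition = NULL,
                              config = group_config(),
                              mixture = strategy_mixture(TRIGGER = 1),
                              endgame_max = 0.3, seed = 1) {
  preset <- match.arg(preset)
  groups_per_condition <- switch(preset,
                                 exp1 = 7L, exp2 = 6L,
                                 custom = {
                                   if (is.null(groups_per_condition)) {
                                     stop("`groups_per_condition` is required for a custom design",
                                          call. = FALSE)
                                   }
                                   as.integer(groups_per_condition)
                                 })
  stopifnot(inherits(config, "group_config"),
            inherits(mixture, "strategy_mixture"))
  if (!is.numeric(endgame_max) || endgame_max < 0 || endgame_max > 1) {
    stop("`endgame_max` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(experiment = preset, groups_per_condition = groups_per_condition,
                 config = config, mixture = mixture,
                 endgame_max = endgame_max, seed = as.integer(seed)),
            class = "experiment_design")
}

# Extra defection probability per period: linear ramp over the last 5.
endgame_ramp <- function(periods, endgame_max) {
  ramp <- numeric(periods)
  if (endgame_max > 0 && periods >= 5) {
    t <- (periods - 4):periods
    ramp[t] <- endgame_max * (t - (periods - 4)) / 4
  }
  ramp
}

#' Generate a synthetic experiment dataset
#'
#' Runs one independent [run_group()] per group of the design, drawing each
#' actor's strategy from the design's mixture, and returns the flat
#' dyad-period table the analysis stage consumes.
#'
#' @param design An [experiment_design()].
#' @param payoffs A [pd_payoffs()].
#' @return A data frame (class `"experiment_dataset"`) with columns
#'   `experiment`, `group`, `condition`, `period`, `actor_a`, `actor_b`,
#'   `action_a`, `action_b`, `payoff_a`, `payoff_b`; `n * m / 2` rows per
#'   group and period. Group ids encode experiment, condition, and index.
#' @examples
#' d <- generate_experiment(experiment_design("exp2", seed = 1))
#' nrow(d)  # 12 groups x 40 periods x 6 dyads = 2880
#' @export
generate_experiment <- function(design, payoffs = pd_payoffs()) {
  stopifnot(inherits(design, "experiment_design"))
  cfg <- design$config
  ramp <- endgame_ramp(cfg$periods, design$endgame_max)
  use_ramp <- if (any(ramp > 0)) ramp else NULL
  out <- vector("list", 2L * design$groups_per_condition)
  gi <- 0L
  for (condition in c("atomized", "embedded")) {
    gcfg <- group_config(cfg$n, cfg$m, cfg$periods, condition)
    # the sub-seed is keyed by condition and within-condition index, so a
    # design with more groups per condition reproduces the existing ones
    cond_offset <- if (condition == "embedded") 500000L else 0L
    for (g in seq_len(design$groups_per_condition)) {
      gi <- gi + 1L
      gseed <- derive_seed(design$seed, cond_offset + g)
      strategies <- with_seed(gseed, {
        idx <- sample.int(length(design$mixture$specs), gcfg$n,
                          replace = TRUE, prob = design$mixture$weights)
        design$mixture$specs[idx]
      })
      rec <- run_group(gcfg, payoffs, strategies,
                       seed = derive_seed(gseed, 1L),
                       extra_defect_prob = use_ramp)
      out[[gi]] <- data.frame(
        experiment = design$experiment,
        group = sprintf("%s.%s.g%02d", design$experiment, condition, g),
        condition = condition,
        rec[, c("period", "actor_a", "actor_b", "action_a", "action_b",
                "payoff_a", "payoff_b")],
        stringsAsFactors = FALSE)
    }
  }
  ds <- do.call(rbind, out)
  rownames(ds) <- NULL
  class(ds) <- c("experiment_dataset", "data.frame")
  ds
}

#' Write / read an experiment dataset as CSV
#'
#' The on-disk format is plain UTF-8 CSV with a header row and one matched
#' dyad-period per row. On read, the lab action labels `ORANGE` (cooperate)
#' and `BLUE` (defect) are normalized to `C`/`D`, and the structural
#' invariants of the format are validated (see [validate_dataset()]).
#'
#' @param dataset An experiment dataset data frame.
#' @param path File path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns
#'   the validated dataset.
#' @examples
#' d <- generate_experiment(experiment_design("exp2", seed = 1))
#' f <- tempfile(fileext = ".csv")
#' write_dataset(d, f)
#' identical(read_dataset(f), d)
#' @export
write_dataset <- function(dataset, path) {
  missing_cols <- setdiff(dataset_columns, names(dataset))
  if (length(missing_cols) > 0L) {
    stop("dataset lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(as.data.frame(dataset)[, dataset_columns], path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  ds <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(dataset_columns, names(ds))
  if (length(missing_cols) > 0L) {
    stop("malformed dataset file, missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ds <- ds[, dataset_columns]
  for (col in c("period", "actor_a", "actor_b")) ds[[col]] <- as.integer(ds[[col]])
  for (col in c("payoff_a", "payoff_b")) ds[[col]] <- as.numeric(ds[[col]])
  ds$action_a <- normalize_actions(ds$action_a)
  ds$action_b <- normalize_actions(ds$action_b)
  validate_dataset(ds)
  class(ds) <- c("experiment_dataset", "data.frame")
  ds
}

#' Validate the structural invariants of an experiment dataset
#'
#' Checks, with row-level diagnostics naming group, period, and actor:
#' a single condition per group; complete periods `1..max`; exactly
#' `n * m / 2` dyads per group-period with every actor matched exactly `m`
#' times; no self-pairs or duplicate dyads; actions in `C`/`D`.
#'
#' @param dataset The dataset data frame.
#' @param m Expected per-period degree of every actor; `NULL` (default)
#'   infers it per group from the first period's dyad count.
#' @return The dataset, invisibly, if valid; otherwise an error.
#' @export
validate_dataset <- function(dataset, m = NULL) {
  problems <- character(0)
  if (any(dataset$actor_a == dataset$actor_b)) {
    problems <- c(problems, "self-paired dyads present")
  }
  for (g in unique(dataset$group)) {
    dg <- dataset[dataset$group == g, ]
    if (length(unique(dg$condition)) != 1L) {
      problems <- c(problems,
                    sprintf("group %s: condition not constant within group", g))
    }
    periods <- sort(unique(dg$period))
    if (!identical(periods, seq_len(max(periods)))) {
      problems <- c(problems, sprintf("group %s: incomplete period sequence", g))
    }
    actors <- sort(unique(c(dg$actor_a, dg$actor_b)))
    n <- length(actors)
    m_g <- if (is.null(m)) 2L * sum(dg$period == periods[1L]) / n else m
    if (m_g < 1 || m_g != round(m_g)) {
      problems <- c(problems,
                    sprintf("group %s: dyad count of period 1 implies non-integer degree", g))
      next
    }
    for (t in periods) {
      dt <- dg[dg$period == t, ]
      if (nrow(dt) != n * m_g / 2) {
        problems <- c(problems,
                      sprintf("group %s, period %d: %d dyads, expected %d",
                              g, t, nrow(dt), n * m_g / 2))
      }
      key <- paste(pmin(dt$actor_a, dt$actor_b), pmax(dt$actor_a, dt$actor_b))
      if (anyDuplicated(key)) {
        problems <- c(problems,
                      sprintf("group %s, period %d: duplicate dyads", g, t))
      }
      deg <- table(factor(c(dt$actor_a, dt$actor_b), levels = actors))
      bad <- names(deg)[deg != m_g]
      if (length(bad) > 0L) {
        problems <- c(problems,
                      sprintf("group %s, period %d: actor %s matched %s times, expected %d",
                              g, t, bad, deg[bad], m_g))
      }
    }
  }
  if (length(problems) > 0L) {
    stop("invalid experiment dataset:\n  ",
         paste(utils::head(problems, 20L), collapse = "\n  "), call. = FALSE)
  }
  invisible(dataset)
}
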