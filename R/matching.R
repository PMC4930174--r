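# Uniform sampling of labeled m-regular interaction graphs.
#
# Two exact routes:
#   * n <= 8: enumerate all labeled m-regular graphs once (cached), then draw
#     an index uniformly.
#   * n > 8: pairing-model rejection. A stub permutation conditioned on
#     yielding a simple graph is uniform over simple m-regular graphs, because
#     every simple labeled m-regular graph corresponds to exactly (m!)^n stub
#     pairings.

.matching_cache <- new.env(parent = emptyenv())

# All labeled m-regular graphs on n vertices, as a list of k x 2 matrices
# (k = n*m/2, rows sorted, a < b). Each graph appears exactly once: the
# smallest vertex with remaining degree is always completed first, and its
# partners are chosen among higher-unfinished vertices.
enumerate_matchings <- function(n, m) {
  check_n_m(n, m)
  key <- paste(n, m, sep = ":")
  if (!is.null(.matching_cache[[key]])) return(.matching_cache[[key]])
  res <- list()
  recurse <- function(deg, edges) {
    open <- which(deg > 0L)
    if (length(open) == 0L) {
      g <- do.call(rbind, edges)
      g <- g[order(g[, 1L], g[, 2L]), , drop = FALSE]
      res[[length(res) + 1L]] <<- g
      return(invisible(NULL))
    }
    v <- open[1L]
    cand <- open[open > v]
    k <- deg[v]
    if (length(cand) < k) return(invisible(NULL))
    sels <- utils::combn(cand, k, simplify = FALSE)
    for (sel in sels) {
      d2 <- deg
      d2[v] <- 0L
      d2[sel] <- d2[sel] - 1L
      recurse(d2, c(edges, list(cbind(v, sel, deparse.level = 0))))
    }
  }
  recurse(rep.int(as.integer(m), n), list())
  .matching_cache[[key]] <- res
  res
}

#' Sample a uniform m-regular matching
#'
#' Draw one period's interaction graph: a labeled m-regular graph on `n`
#' actors, each such graph with equal probability. For `n <= 8` the full set
#' of graphs is enumerated once and cached, and a graph is drawn by uniform
#' index; for larger `n` a stub-pairing (configuration model) sampler with
#' rejection of self-loops and multi-edges is used, which is also exactly
#' uniform over simple m-regular graphs.
#'
#' Uses the R random number generator; seed via [set.seed()] for
#' reproducibility.
#'
#' @inheritParams group_config
#' @param method `"auto"` (enumeration for `n <= 8`, pairing otherwise),
#'   `"enumerate"`, or `"pairing"`.
#' @return An object of class `"matching"`: an integer matrix with `n*m/2`
#'   rows and columns `a`, `b` (`a < b`, rows sorted), one row per matched
#'   dyad.
#' @examples
#' set.seed(1)
#' sample_matching(6, 2)
#' @export
sample_matching <- function(n, m, method = c("auto", "enumerate", "pairing")) {
  method <- match.arg(method)
  check_n_m(n, m)
  n <- as.integer(n); m <- as.integer(m)
  if (method == "auto") method <- if (n <= 8L) "enumerate" else "pairing"
  if (method == "enumerate") {
    all <- enumerate_matchings(n, m)
    g <- all[[sample.int(length(all), 1L)]]
  } else {
    g <- sample_matching_pairing(n, m)
  }
  structure(g, dimnames = list(NULL, c("a", "b")), class = "matching",
            n = n, m = m)
}

sample_matching_pairing <- function(n, m, max_tries = 100000L) {
  stubs <- rep.int(seq_len(n), m)
  for (try in seq_len(max_tries)) {
    s <- sample(stubs)
    a <- s[seq(1L, length(s), by = 2L)]
    b <- s[seq(2L, length(s), by = 2L)]
    lo <- pmin(a, b); hi <- pmax(a, b)
    if (any(lo == hi)) next
    key <- (lo - 1L) * n + hi
    if (anyDuplicated(key)) next
    o <- order(lo, hi)
    return(cbind(lo, hi, deparse.level = 0)[o, , drop = FALSE])
  }
  stop("pairing sampler failed to produce a simple graph; (n, m) too dense?",
       call. = FALSE)
}

#' @export
print.matching <- function(x, ...) {
  cat(sprintf("%d-regular matching on %d actors (%d dyads):\n",
              attr(x, "m"), attr(x, "n"), nrow(x)))
  cat(paste(sprintf("  %d-%d", x[, 1L], x[, 2L]), collapse = " "), "\n")
  invisible(x)
}

# Canonical string key of a matching, for support/uniformity checks.
matching_key <- function(g) paste(g[, 1L], g[, 2L], sep = "-", collapse = ";")

validate_matching <- function(g, n, m) {
  deg <- tabulate(c(g[, 1L], g[, 2L]), nbins = n)
  if (any(g[, 1L] == g[, 2L])) stop("matching contains a self-pair", call. = FALSE)
  if (anyDuplicated(paste(pmin(g[, 1L], g[, 2L]), pmax(g[, 1L], g[, 2L])))) {
    stop("matching contains a duplicate pair", call. = FALSE)
  }
  if (!all(deg == m)) {
    stop("matching is not m-regular", call. = FALSE)
  }
  invisible(TRUE)
}
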