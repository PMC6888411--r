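#' Global Moran's I on an areal graph
#'
#' Computes the global spatial autocorrelation statistic
#' \deqn{I = \frac{N}{S_0} \frac{\sum_i \sum_j w_{ij} z_i z_j}{\sum_i z_i^2},}
#' with \eqn{z_i = x_i - \bar x} and \eqn{S_0 = \sum_{ij} w_{ij}}, using the
#' binary (unstandardised) adjacency weights of `graph`. Positive values
#' indicate clustering of similar values among neighbouring regions.
#'
#' @param values numeric vector, one value per region in `graph` order.
#' @param graph a [region_graph()].
#' @return Moran's I (scalar).
#' @examples
#' g <- study7_graph()
#' morans_i(rnorm(7), g)
#' @export
morans_i <- function(values, graph) {
  stopifnot(inherits(graph, "region_graph"))
  n <- graph$n_regions
  if (length(values) != n) {
    stop("values has length ", length(values), " but graph has ", n, " regions")
  }
  if (n < 2L) stop("Moran's I needs at least 2 regions")
  if (!all(is.finite(values))) stop("values must be finite")
  z <- values - mean(values)
  ss <- sum(z^2)
  if (ss == 0) stop("zero variance; Moran's I undefined")
  s0 <- sum(graph$W)
  if (s0 == 0) stop("graph has no edges; Moran's I undefined")
  (n / s0) * drop(crossprod(z, graph$W %*% z)) / ss
}

#' Permutation test for Moran's I
#'
#' Monte-Carlo permutation test for positive spatial autocorrelation: the
#' observed I is compared with its distribution under random relabelling of
#' the regions, and the one-sided p-value is
#' `(1 + #\{I* >= I_obs\}) / (1 + n_perm)`. Exact under exchangeability and
#' assumption-free at small N, which is why it is the default screening test
#' here (the normal approximation is poor at N = 7).
#'
#' @inheritParams morans_i
#' @param n_perm number of permutations (at least 99; default 9999).
#' @param seed integer seed; the result is reproducible for a fixed seed.
#' @return list with elements `I` (observed statistic), `p` (one-sided
#'   p-value), `n_perm`.
#' @export
morans_i_test <- function(values, graph, n_perm = 9999L, seed = 1L) {
  if (n_perm < 99L) stop("insufficient permutations (need n_perm >= 99)")
  i_obs <- morans_i(values, graph)
  perm_stat <- local({
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(as.integer(seed))
    vapply(seq_len(n_perm),
           function(k) morans_i(sample(values), graph), numeric(1))
  })
  p <- (1 + sum(perm_stat >= i_obs)) / (1 + n_perm)
  list(I = i_obs, p = p, n_perm = as.integer(n_perm))
}

# Restore (or clear) the global RNG state saved before a seeded computation,
# so seeded helpers do not clobber the caller's RNG stream.
restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Moran's I screening table for a prevalence panel
#'
#' Reproduces the global-clustering screening step: per wave (and per sex,
#' when present) the crude prevalence `cases/total` across regions is tested
#' for positive spatial autocorrelation.
#'
#' @param panel a [panel_counts()] object.
#' @param n_perm,seed passed to [morans_i_test()].
#' @return data.frame with columns `year`, `sex`, `moran_i`, `p_value`.
#' @export
moran_screening <- function(panel, n_perm = 9999L, seed = 1L) {
  stopifnot(inherits(panel, "panel_counts"))
  rows <- list()
  for (j in seq_len(panel$n_sexes)) {
    for (t in seq_along(panel$waves)) {
      prev <- panel$O[j, , t] / panel$n[j, , t]
      res <- morans_i_test(prev, panel$graph, n_perm = n_perm,
                           seed = as.integer(seed) + 131L * t + j)
      rows[[length(rows) + 1L]] <- data.frame(
        year = panel$waves[t],
        sex = panel$sexes[j],
        moran_i = res$I,
        p_value = res$p
      )
    }
  }
  do.call(rbind, rows)
}
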