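# Independent oracles used across the suite. These deliberately re-derive
# each quantity from its definition (double loops, dense matrices, the
# Cox-de Boor recurrence) rather than calling the package's own code paths.

# Moran's I by the naive double loop over all (i, j) pairs.
moran_brute <- function(values, W) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0
  s0 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + W[i, j] * z[i] * z[j]
      s0 <- s0 + W[i, j]
    }
  }
  (n / s0) * num / sum(z^2)
}

# Random connected graph on n nodes: a random spanning tree plus extra edges.
random_connected_graph <- function(n, extra = 2L) {
  ids <- paste0("r", seq_len(n))
  edges <- cbind(ids[2:n], ids[vapply(2:n, function(i) {
    sample.int(i - 1L, 1L)
  }, 1L)])
  for (k in seq_len(extra)) {
    pair <- sample(ids, 2L)
    if (pair[1L] != pair[2L]) edges <- rbind(edges, pair)
  }
  region_graph(ids, edges)
}

# Cubic B-spline basis via a direct implementation of the Cox-de Boor
# recurrence on the clamped knot vector (independent of splines::splineDesign).
cox_de_boor_basis <- function(x, interior, lo, hi) {
  knots <- c(rep(lo, 4L), interior, rep(hi, 4L))
  nb <- length(knots) - 4L
  deg0 <- function(t) {
    vapply(seq_len(length(knots) - 1L), function(i) {
      if (knots[i] <= t && t < knots[i + 1L]) 1 else 0
    }, numeric(1))
  }
  basis_at <- function(t) {
    if (t == hi) {
      # closed right end: B-splines are left-continuous at the last knot
      out <- numeric(nb)
      out[nb] <- 1
      return(out)
    }
    Bprev <- deg0(t)
    for (d in 1:3) {
      Bcur <- numeric(length(Bprev) - 1L)
      for (i in seq_along(Bcur)) {
        left <- 0
        if (knots[i + d] > knots[i]) {
          left <- (t - knots[i]) / (knots[i + d] - knots[i]) * Bprev[i]
        }
        right <- 0
        if (knots[i + d + 1L] > knots[i + 1L]) {
          right <- (knots[i + d + 1L] - t) /
            (knots[i + d + 1L] - knots[i + 1L]) * Bprev[i + 1L]
        }
        Bcur[i] <- left + right
      }
      Bprev <- Bcur
    }
    Bprev
  }
  t(vapply(x, basis_at, numeric(nb)))
}

# Dense graph Laplacian-style matrix D - W.
laplacian_matrix <- function(graph) {
  diag(graph$D) - graph$W
}

# Small study-like SCM/BYM fixtures for fast MCMC tests.
fast_mcmc <- function(seed = 1L, n_iter = 1500L) {
  mcmc_config(n_chains = 2L, n_iter = n_iter, burn_in = n_iter %/% 2L,
              thin = 2L, seed = seed)
}

random_bym_params <- function(N, K, seed = 1L) {
  set.seed(seed)
  G <- crossprod(matrix(rnorm(K * K), K)) + diag(K)
  bym_params(
    alpha0 = rnorm(1), a = rnorm(K),
    u0 = rnorm(N, 0, 0.3),
    s0 = { s <- rnorm(N, 0, 0.3); s - mean(s) },
    b_spline = { b <- matrix(rnorm(N * K, 0, 0.2), N, K)
                 sweep(b, 2L, colMeans(b)) },
    tau_u = rgamma(1, 3, 1) + 0.5, tau_s = rgamma(1, 3, 1) + 0.5,
    Gamma = G
  )
}

random_scm_params <- function(N, K, T_, seed = 1L) {
  set.seed(seed)
  G <- crossprod(matrix(rnorm(K * K), K)) + diag(K)
  ctr_cols <- function(m) sweep(m, 2L, colMeans(m))
  rs <- array(rnorm(2 * N * K, 0, 0.2), c(2, N, K))
  for (j in 1:2) rs[j, , ] <- ctr_cols(matrix(rs[j, , ], N, K))
  scm_params(
    alpha = rnorm(2), a_gender = matrix(rnorm(2 * K), 2, K),
    b0 = rnorm(N, 0, 0.3),
    b_shared_spline = ctr_cols(matrix(rnorm(N * K, 0, 0.2), N, K)),
    b_gender = matrix(rnorm(2 * N, 0, 0.3), 2, N),
    beta_gender_spline = rs,
    beta_it = ctr_cols(matrix(rnorm(N * T_, 0, 0.2), N, T_)),
    log_delta = rnorm(T_, 0, 0.3),
    tau_beta = rgamma(1, 3, 1) + 0.5, tau_b = rgamma(1, 3, 1) + 0.5,
    Gamma_b = G
  )
}

random_two_sex_panel <- function(graph, waves, seed = 1L) {
  set.seed(seed)
  N <- graph$n_regions; T_ <- length(waves)
  n <- array(sample(100:400, 2 * N * T_, replace = TRUE), c(2, N, T_))
  O <- array(rbinom(2 * N * T_, as.vector(n), 0.2), c(2, N, T_))
  panel_counts(graph, waves, O, n, sexes = c("m", "f"))
}
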