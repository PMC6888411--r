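#' Intrinsic CAR (ICAR) log-density
#'
#' Log-density of the intrinsic conditional autoregressive prior on an
#' areal graph, up to its constant:
#' \deqn{\log \pi(x \mid \tau) = \frac{N-1}{2}\log\tau -
#'   \frac{\tau}{2}\sum_{i \sim j}(x_i - x_j)^2,}
#' the sum running over unordered neighbour pairs. The prior is improper and
#' defined on the sum-to-zero subspace, so `x` must (numerically) sum to
#' zero.
#'
#' @param x length-N vector summing to zero.
#' @param tau positive precision.
#' @param graph a [region_graph()]; must have no isolated region.
#' @param include_normalizer include the `(N-1)/2 log(tau)` term (default);
#'   set `FALSE` to get the bare quadratic kernel.
#' @return scalar log-density (up to a constant).
#' @export
log_icar <- function(x, tau, graph, include_normalizer = TRUE) {
  stopifnot(inherits(graph, "region_graph"))
  validate_car_graph(graph)
  N <- graph$n_regions
  if (length(x) != N) stop("x must have length ", N)
  if (tau <= 0) stop("tau must be positive")
  if (abs(sum(x)) > 1e-6 * (1 + max(abs(x)))) {
    stop("x must sum to zero (intrinsic CAR is defined on that subspace)")
  }
  q <- icar_quadform(x, graph)
  kern <- -(tau / 2) * q
  if (include_normalizer) kern + (N - 1) / 2 * log(tau) else kern
}

# Sum over unordered neighbour pairs of (x_i - x_j)^2, via the edge list.
icar_quadform <- function(x, graph) {
  idx <- which(upper.tri(graph$W) & graph$W == 1L, arr.ind = TRUE)
  sum((x[idx[, 1L]] - x[idx[, 2L]])^2)
}

#' Intrinsic multivariate CAR (MCAR) log-density
#'
#' Log-density, up to a constant, of the matrix of random spline
#' coefficients `b` (regions by basis columns) under the intrinsic MCAR
#' prior with precision `(D - W) \otimes Gamma`:
#' \deqn{\frac{N-1}{2}\log|\Gamma| - \frac12 \sum_{i \sim j}
#'   (b_{i\cdot} - b_{j\cdot}) \Gamma (b_{i\cdot} - b_{j\cdot})^\top.}
#' Defined on the per-column sum-to-zero subspace.
#'
#' @param b N x K matrix, each column summing to zero.
#' @param Gamma K x K symmetric positive-definite precision.
#' @param graph a [region_graph()].
#' @param include_normalizer include the `(N-1)/2 log|Gamma|` term.
#' @return scalar log-density (up to a constant).
#' @export
log_mcar <- function(b, Gamma, graph, include_normalizer = TRUE) {
  stopifnot(inherits(graph, "region_graph"), is.matrix(b))
  validate_car_graph(graph)
  N <- graph$n_regions
  if (nrow(b) != N) stop("b must have ", N, " rows")
  check_spd(Gamma, "Gamma")
  if (ncol(b) != nrow(Gamma)) stop("ncol(b) must match dim(Gamma)")
  cs <- colSums(b)
  if (any(abs(cs) > 1e-6 * (1 + max(abs(b))))) {
    stop("each column of b must sum to zero")
  }
  idx <- which(upper.tri(graph$W) & graph$W == 1L, arr.ind = TRUE)
  q <- 0
  for (r in seq_len(nrow(idx))) {
    d <- b[idx[r, 1L], ] - b[idx[r, 2L], ]
    q <- q + drop(d %*% Gamma %*% d)
  }
  kern <- -q / 2
  if (include_normalizer) {
    as.numeric(kern +
                 (N - 1) / 2 * determinant(Gamma, logarithm = TRUE)$modulus)
  } else kern
}

# Log prior density of a scalar precision tau under the configured
# sensitivity variant (includes the Jacobian of the reparameterisation).
log_tau_prior <- function(tau, prior) {
  if (tau <= 0) return(-Inf)
  switch(prior$precision_prior,
    gamma_prec = stats::dgamma(tau, shape = prior$tau_shape,
                               rate = prior$tau_rate, log = TRUE),
    unif_sd = {
      # sigma = tau^(-1/2) ~ U(0, 1)  =>  tau >= 1, |dsigma/dtau| = tau^(-3/2)/2
      if (tau < 1) -Inf else log(0.5) - 1.5 * log(tau)
    },
    halfnormal_var = {
      # sigma^2 = 1/tau ~ N(0, 100) I(0,), |dv/dtau| = tau^(-2)
      v <- 1 / tau
      log(2) - 0.5 * log(2 * pi * 100) - v^2 / 200 - 2 * log(tau)
    }
  )
}

# Wishart(R^-1, df) log kernel in the BUGS parameterisation:
# ((df - K - 1)/2) log|G| - tr(R G)/2, up to a constant.
log_wishart_kernel <- function(G, R, df) {
  K <- nrow(G)
  ld <- determinant(G, logarithm = TRUE)$modulus
  as.numeric((df - K - 1) / 2 * ld - sum(R * G) / 2)
}

wishart_defaults <- function(prior, K) {
  df <- if (is.null(prior$wishart_df)) K else prior$wishart_df
  R <- if (is.null(prior$wishart_R)) diag(K) else prior$wishart_R
  if (df < K) stop("wishart_df must be >= K")
  if (!identical(dim(R), c(K, K))) stop("wishart_R must be K x K")
  list(df = df, R = R)
}

binom_loglik <- function(O, n, eta) {
  p <- stats::plogis(eta)
  sum(stats::dbinom(O, n, p, log = TRUE))
}

#' Log joint density of the spatio-temporal BYM model
#'
#' Binomial log-likelihood at [bym_linear_predictor()] plus every prior
#' term (ICAR on `s0`, iid normals on `u0`, MCAR on the random spline
#' coefficients, gamma priors on the precisions, vague normals on the fixed
#' effects, Wishart on the MCAR precision), up to a constant. Terms absent
#' from `spec` are skipped, as are priors for parameter blocks left `NULL`.
#'
#' @param params a [bym_params()].
#' @param data a single-sex [panel_counts()].
#' @param basis a [build_basis()] result.
#' @param prior a [prior_config()].
#' @param spec a [model_spec()] (default: full BYM).
#' @return scalar log joint density (up to a constant); `-Inf` when the
#'   likelihood is degenerate.
#' @export
log_joint_bym <- function(params, data, basis, prior = prior_config(),
                          spec = model_spec("bym")) {
  stopifnot(inherits(params, "bym_params"), inherits(data, "panel_counts"),
            data$n_sexes == 1L)
  X <- covariate_design(spec, data, basis)
  eta <- bym_linear_predictor(params, basis, X)
  lj <- binom_loglik(data$O[1L, , ], data$n[1L, , ], eta)
  sdf <- sqrt(prior$fixed_effect_var)
  lj <- lj + stats::dnorm(params$alpha0, 0, sdf, log = TRUE)
  if (has_term(spec, "fixed_spline") && length(params$a)) {
    lj <- lj + sum(stats::dnorm(params$a, 0, sdf, log = TRUE))
  }
  if (has_term(spec, "unstructured") && length(params$u0)) {
    lj <- lj + sum(stats::dnorm(params$u0, 0, 1 / sqrt(params$tau_u),
                                log = TRUE)) +
      log_tau_prior(params$tau_u, prior)
  }
  if (has_term(spec, "spatial") && length(params$s0)) {
    lj <- lj + log_icar(params$s0, params$tau_s, data$graph) +
      log_tau_prior(params$tau_s, prior)
  }
  if (has_term(spec, "random_spline") && !is.null(params$b_spline)) {
    wd <- wishart_defaults(prior, basis$K)
    lj <- lj + log_mcar(params$b_spline, params$Gamma, data$graph) +
      log_wishart_kernel(params$Gamma, wd$R, wd$df)
  }
  if (!is.null(params$beta_cov) && length(X)) {
    lj <- lj + sum(stats::dnorm(params$beta_cov, 0, sdf, log = TRUE))
  }
  as.numeric(lj)
}

#' Log joint density of the spatio-temporal shared component model
#'
#' Binomial log-likelihood over both sexes at [scm_linear_predictor()] plus
#' every prior term: per-wave ICAR on the interaction `beta_it`, MCAR on the
#' shared random spline coefficients, per-column ICAR (precision `tau_b`)
#' on the gender-specific random spline coefficients, vague normals on
#' `b_0i` and `b_ji`, `N(0, 0.169)`-variance normals on `log delta_t`,
#' gamma priors on `tau_beta`/`tau_b`, vague normals on the fixed effects
#' and a Wishart on the MCAR precision, up to a constant.
#'
#' @param params a [scm_params()].
#' @param data a two-sex [panel_counts()].
#' @param basis a [build_basis()] result.
#' @param prior a [prior_config()].
#' @param spec a [model_spec()] (default: full SCM).
#' @return scalar log joint density (up to a constant).
#' @export
log_joint_scm <- function(params, data, basis, prior = prior_config(),
                          spec = model_spec("scm")) {
  stopifnot(inherits(params, "scm_params"), inherits(data, "panel_counts"),
            data$n_sexes == 2L)
  X <- covariate_design(spec, data, basis)
  lp <- scm_linear_predictor(params, basis, X)
  lj <- binom_loglik(data$O[1L, , ], data$n[1L, , ], lp[1L, , ]) +
    binom_loglik(data$O[2L, , ], data$n[2L, , ], lp[2L, , ])
  sdf <- sqrt(prior$fixed_effect_var)
  lj <- lj + sum(stats::dnorm(params$alpha, 0, sdf, log = TRUE))
  if (!is.null(params$a_gender) && has_term(spec, "gender_spline_fixed")) {
    lj <- lj + sum(stats::dnorm(params$a_gender, 0, sdf, log = TRUE))
  }
  if (length(params$b0) && has_term(spec, "shared_spatial")) {
    lj <- lj + sum(stats::dnorm(params$b0, 0, sdf, log = TRUE))
  }
  if (!is.null(params$b_gender) && has_term(spec, "gender_spatial")) {
    lj <- lj + sum(stats::dnorm(params$b_gender, 0, sdf, log = TRUE))
  }
  if (!is.null(params$b_shared_spline) && has_term(spec, "shared_spline")) {
    wd <- wishart_defaults(prior, basis$K)
    lj <- lj + log_mcar(params$b_shared_spline, params$Gamma_b, data$graph) +
      log_wishart_kernel(params$Gamma_b, wd$R, wd$df)
  }
  if (!is.null(params$beta_gender_spline) &&
      has_term(spec, "gender_spline_random")) {
    for (j in 1:2) {
      for (k in seq_len(basis$K)) {
        lj <- lj + log_icar(params$beta_gender_spline[j, , k],
                            params$tau_b, data$graph)
      }
    }
    lj <- lj + log_tau_prior(params$tau_b, prior)
  }
  if (!is.null(params$beta_it) && has_term(spec, "interaction")) {
    for (t in seq_len(ncol(params$beta_it))) {
      lj <- lj + log_icar(params$beta_it[, t], params$tau_beta, data$graph)
    }
    lj <- lj + log_tau_prior(params$tau_beta, prior)
  }
  if (length(params$log_delta) && has_term(spec, "delta_weights")) {
    lj <- lj + sum(stats::dnorm(params$log_delta, 0,
                                sqrt(prior$log_delta_var), log = TRUE))
  }
  if (!is.null(params$beta_cov) && length(X)) {
    lj <- lj + sum(stats::dnorm(params$beta_cov, 0, sdf, log = TRUE))
  }
  as.numeric(lj)
}
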