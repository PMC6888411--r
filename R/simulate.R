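#' Truth configuration for the synthetic panel generator
#'
#' Describes a generating model with known latent truth: which model, the
#' graph and waves, how the per-cell totals arise, which parameter blocks
#' are fixed at supplied values and which are drawn from their priors at
#' given precisions, and (optionally) how regional covariates evolve. The
#' defaults emulate the structure of the multi-wave survey behind the
#' package: 7 contiguous provinces, 9 waves from 1991 to 2015, and cell
#' totals in the hundreds to low thousands.
#'
#' @param model `"bym"` or `"scm"`.
#' @param graph a [region_graph()] (default [study7_graph()]).
#' @param waves calendar years (default the 9 study waves).
#' @param interior_knots interior knots of the generating spline basis
#'   (default one knot at the centred reference year, 0).
#' @param center_year centring year (default 2004).
#' @param n_range totals are drawn uniformly from this integer range per
#'   sex-region-wave (default 200..1500).
#' @param fixed named list of parameter blocks held at supplied values
#'   (any field of [bym_params()] / [scm_params()]).
#' @param effect_tau named list of precisions for blocks drawn from their
#'   priors at simulation time. Recognised names for BYM: `u0`, `s0`
#'   (ICAR), `b_spline` (MCAR, scalar precision times identity); for SCM:
#'   `b0`, `b_gender`, `b_shared_spline`, `beta_gender_spline`, `beta_it`
#'   (ICAR per wave). A block absent from both `fixed` and `effect_tau` is
#'   zero.
#' @param covariate_gen `NULL`, or a list with `baseline` and `drift`
#'   (named numeric vectors of start-of-study proportions and total
#'   linear drift over the study period) plus optional `region_sd`
#'   (regional jitter, default 0.03). Proportions are clipped to
#'   `[0.01, 0.99]`.
#' @return object of class `truth_config`.
#' @export
truth_config <- function(model = c("bym", "scm"), graph = study7_graph(),
                         waves = study_waves(), interior_knots = 0,
                         center_year = 2004, n_range = c(200L, 1500L),
                         fixed = list(), effect_tau = list(),
                         covariate_gen = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(graph, "region_graph"))
  if (n_range[1L] < 1L || n_range[2L] < n_range[1L]) {
    stop("n_range must be an increasing pair of totals >= 1")
  }
  structure(
    list(model = model, graph = graph, waves = as.numeric(waves),
         interior_knots = interior_knots, center_year = center_year,
         n_range = as.integer(n_range), fixed = fixed,
         effect_tau = effect_tau, covariate_gen = covariate_gen),
    class = "truth_config"
  )
}

#' The nine study waves
#'
#' @return `c(1991, 1993, 1997, 2000, 2004, 2006, 2009, 2011, 2015)`.
#' @export
study_waves <- function() c(1991, 1993, 1997, 2000, 2004, 2006, 2009, 2011,
                            2015)

# Centre a vector (the generator centres free random-effect levels so the
# intercepts are the identified baselines, matching the sampler's
# constraint handling).
ctr <- function(x) x - mean(x)

# Exact zero-mean ICAR draw via the spectral decomposition of D - W.
ricar_draw <- function(graph, tau) {
  Q <- diag(graph$D) - graph$W
  eg <- eigen(Q, symmetric = TRUE)
  keep <- eg$values > 1e-8
  z <- stats::rnorm(sum(keep)) / sqrt(tau * eg$values[keep])
  drop(eg$vectors[, keep, drop = FALSE] %*% z)
}

# Zero-column-mean MCAR draw with precision (D - W) (x) Gamma.
rmcar_draw <- function(graph, Gamma) {
  Q <- diag(graph$D) - graph$W
  eg <- eigen(Q, symmetric = TRUE)
  keep <- eg$values > 1e-8
  m <- sum(keep)
  K <- nrow(Gamma)
  A <- eg$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(eg$values[keep]), m)
  Z <- matrix(stats::rnorm(m * K), m, K)
  A %*% Z %*% chol(solve(Gamma))
}

sim_covariates <- function(truth) {
  cg <- truth$covariate_gen
  if (is.null(cg)) return(NULL)
  N <- truth$graph$n_regions
  tt <- truth$waves
  frac <- (tt - min(tt)) / diff(range(tt))
  sd_r <- if (is.null(cg$region_sd)) 0.03 else cg$region_sd
  out <- list()
  for (nm in names(cg$baseline)) {
    base <- cg$baseline[[nm]] + stats::rnorm(N, 0, sd_r)
    X <- outer(base, rep(1, length(tt))) +
      outer(rep(1, N), cg$drift[[nm]] * frac)
    out[[nm]] <- pmin(pmax(X, 0.01), 0.99)
  }
  out
}

sim_totals <- function(truth, J) {
  N <- truth$graph$n_regions; T_ <- length(truth$waves)
  array(sample(seq(truth$n_range[1L], truth$n_range[2L]), J * N * T_,
               replace = TRUE), c(J, N, T_))
}

assemble_bym_truth <- function(truth, basis) {
  N <- truth$graph$n_regions; K <- basis$K
  fx <- truth$fixed; et <- truth$effect_tau
  get <- function(nm, default) if (!is.null(fx[[nm]])) fx[[nm]] else default
  u0 <- get("u0", if (!is.null(et$u0)) {
    ctr(stats::rnorm(N, 0, 1 / sqrt(et$u0)))
  } else numeric(N))
  s0 <- get("s0", if (!is.null(et$s0)) {
    ricar_draw(truth$graph, et$s0)
  } else numeric(N))
  b <- get("b_spline", if (!is.null(et$b_spline)) {
    rmcar_draw(truth$graph, diag(K) * et$b_spline)
  } else matrix(0, N, K))
  bym_params(
    alpha0 = get("alpha0", 0), a = get("a", numeric(K)),
    u0 = u0, s0 = s0, b_spline = b,
    tau_u = if (!is.null(et$u0)) et$u0 else 1,
    tau_s = if (!is.null(et$s0)) et$s0 else 1,
    Gamma = diag(K) * (if (!is.null(et$b_spline)) et$b_spline else 1),
    beta_cov = fx$beta_cov
  )
}

assemble_scm_truth <- function(truth, basis) {
  N <- truth$graph$n_regions; K <- basis$K; T_ <- length(truth$waves)
  fx <- truth$fixed; et <- truth$effect_tau
  get <- function(nm, default) if (!is.null(fx[[nm]])) fx[[nm]] else default
  b0 <- get("b0", if (!is.null(et$b0)) {
    ctr(stats::rnorm(N, 0, 1 / sqrt(et$b0)))
  } else numeric(N))
  bs <- get("b_shared_spline", if (!is.null(et$b_shared_spline)) {
    rmcar_draw(truth$graph, diag(K) * et$b_shared_spline)
  } else matrix(0, N, K))
  bg <- get("b_gender", if (!is.null(et$b_gender)) {
    t(apply(matrix(stats::rnorm(2 * N, 0, 1 / sqrt(et$b_gender)), 2, N),
            1L, ctr))
  } else matrix(0, 2, N))
  rs <- get("beta_gender_spline", if (!is.null(et$beta_gender_spline)) {
    out <- array(0, c(2, N, K))
    for (j in 1:2) {
      out[j, , ] <- rmcar_draw(truth$graph,
                               diag(K) * et$beta_gender_spline)
    }
    out
  } else array(0, c(2, N, K)))
  bt <- get("beta_it", if (!is.null(et$beta_it)) {
    vapply(seq_len(T_), function(t) ricar_draw(truth$graph, et$beta_it),
           numeric(N))
  } else matrix(0, N, T_))
  scm_params(
    alpha = get("alpha", c(0, 0)),
    a_gender = get("a_gender", matrix(0, 2, K)),
    b0 = b0, b_shared_spline = bs, b_gender = bg,
    beta_gender_spline = rs, beta_it = bt,
    log_delta = get("log_delta", numeric(T_)),
    tau_beta = if (!is.null(et$beta_it)) et$beta_it else 1,
    tau_b = if (!is.null(et$beta_gender_spline)) et$beta_gender_spline else 1,
    Gamma_b = diag(K) *
      (if (!is.null(et$b_shared_spline)) et$b_shared_spline else 1),
    beta_cov = fx$beta_cov
  )
}

#' Simulate a single-sex panel from the BYM generative model
#'
#' Draws any parameter blocks configured with `effect_tau` from their
#' priors, computes the prevalence surface through
#' [bym_linear_predictor()], and draws `O_it ~ Binomial(n_it, p_it)`.
#' Deterministic for a fixed seed.
#'
#' @param truth a [truth_config()] with `model = "bym"`.
#' @param seed integer seed.
#' @return list with `panel` (a [panel_counts()]), `params` (the realised
#'   [bym_params()] truth), `p` (N x T prevalence surface), `basis`.
#' @export
simulate_bym <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "truth_config"), truth$model == "bym")
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  basis <- build_basis(truth$waves, truth$interior_knots, truth$center_year)
  covs <- sim_covariates(truth)
  params <- assemble_bym_truth(truth, basis)
  X <- if (!is.null(params$beta_cov) && !is.null(covs)) {
    covs[names(params$beta_cov)]
  } else NULL
  p <- bym_linear_predictor(params, basis, X, prevalence = TRUE)
  n <- sim_totals(truth, 1L)
  O <- array(stats::rbinom(length(n), as.vector(n),
                           as.vector(array(p, dim(n)))), dim(n))
  panel <- panel_counts(truth$graph, truth$waves, O, n, sexes = "all",
                        covariates = covs)
  list(panel = panel, params = params, p = p, basis = basis)
}

#' Simulate a two-sex panel from the SCM generative model
#'
#' As [simulate_bym()] but with the shared component structure; also
#' returns the true shared weights `delta_t` and the true variance shares
#' `eta_j(t)` computed from the realised latent surfaces.
#'
#' @param truth a [truth_config()] with `model = "scm"`.
#' @param seed integer seed.
#' @return list with `panel` (two sexes), `params`, `p` (2 x N x T),
#'   `delta` (length-T true weights), `eta` (2 x T true variance shares),
#'   `basis`.
#' @export
simulate_scm <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "truth_config"), truth$model == "scm")
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  basis <- build_basis(truth$waves, truth$interior_knots, truth$center_year)
  covs <- sim_covariates(truth)
  params <- assemble_scm_truth(truth, basis)
  X <- if (!is.null(params$beta_cov) && !is.null(covs)) {
    covs[colnames(params$beta_cov)]
  } else NULL
  p <- scm_linear_predictor(params, basis, X, prevalence = TRUE)
  n <- sim_totals(truth, 2L)
  O <- array(stats::rbinom(length(n), as.vector(n), as.vector(p)), dim(n))
  panel <- panel_counts(truth$graph, truth$waves, O, n, sexes = c("m", "f"),
                        covariates = covs)
  eta <- variance_share(params, basis, X)
  list(panel = panel, params = params, p = p,
       delta = exp(params$log_delta), eta = eta, basis = basis)
}

#' Survey-like default truth
#'
#' A documented synthetic truth whose simulated prevalence rises from
#' roughly 0.10-0.13 at the 1991 wave to roughly 0.30-0.38 at 2015, with
#' males above females, on the 7-province graph and the 9 study waves. The
#' gender-specific logit trends are linear between the printed anchor
#' prevalences (males 0.128 to 0.381, females 0.108 to 0.315, pooled 0.117
#' to 0.345), projected onto the generating spline basis; all latent
#' parameter values are invented (the real latent truth is unknowable) and
#' sized so province effects span roughly +/-0.3 on the log-odds scale.
#'
#' @param model `"scm"` (default, both sexes) or `"bym"` (pooled single
#'   outcome).
#' @param with_covariates include the four drifting regional covariates
#'   (proportions aged 60+, overweight, ever-smokers, drinkers) in the
#'   generated panels (their true coefficients are zero unless overridden
#'   via `fixed$beta_cov`).
#' @return a [truth_config()].
#' @export
chns_like_preset <- function(model = c("scm", "bym"),
                             with_covariates = FALSE) {
  model <- match.arg(model)
  waves <- study_waves()
  basis <- build_basis(waves, interior_knots = 0, center_year = 2004)
  anchor_curve <- function(p0, p1) {
    tv <- basis$t_values
    l0 <- stats::qlogis(p0); l1 <- stats::qlogis(p1)
    l0 + (l1 - l0) * (tv - min(tv)) / diff(range(tv))
  }
  # With the first clamped basis column dropped, every remaining column is
  # zero at the first wave, so the intercept is the first-wave logit level
  # and the trend (exactly representable once it vanishes at the boundary)
  # is projected onto the basis.
  proj <- function(curve, alpha) {
    stats::coef(stats::lm.fit(basis$B, curve - alpha))
  }
  cov_gen <- if (with_covariates) {
    list(
      baseline = c(age60plus = 0.10, overweight = 0.15,
                   ever_smoker = 0.30, drinker = 0.30),
      drift = c(age60plus = 0.10, overweight = 0.25,
                ever_smoker = -0.05, drinker = 0.05),
      region_sd = 0.03
    )
  } else NULL
  if (model == "bym") {
    curve <- anchor_curve(0.117, 0.345)
    alpha0 <- curve[1L]
    truth_config(
      model = "bym",
      fixed = list(alpha0 = alpha0, a = proj(curve, alpha0)),
      effect_tau = list(u0 = 44, s0 = 25, b_spline = 100),
      covariate_gen = cov_gen
    )
  } else {
    cm <- anchor_curve(0.128, 0.381)
    cf <- anchor_curve(0.108, 0.315)
    alpha <- c(cm[1L], cf[1L])
    truth_config(
      model = "scm",
      fixed = list(alpha = alpha,
                   a_gender = rbind(proj(cm, alpha[1L]),
                                    proj(cf, alpha[2L])),
                   log_delta = numeric(length(waves))),
      effect_tau = list(b0 = 44, b_shared_spline = 100, b_gender = 25,
                        beta_gender_spline = 100, beta_it = 100),
      covariate_gen = cov_gen
    )
  }
}
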