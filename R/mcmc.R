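#' MCMC run configuration
#'
#' The documented full-run protocol is 2 chains of 100,000 iterations with a
#' 50,000-iteration burn-in keeping every 10th draw; [mcmc_config_desk()]
#' gives the desk-scale settings used throughout the test-suite
#' (2 chains x 4,000 iterations, 2,000 burn-in, thin 2).
#'
#' @param n_chains number of chains (>= 2 for Brooks-Gelman-Rubin
#'   diagnostics).
#' @param n_iter total iterations per chain.
#' @param burn_in discarded initial iterations (`< n_iter`).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer seed; fits are bit-reproducible given the seed.
#' @param init `"jitter"` (default: zeros plus small normal noise),
#'   `"zeros"`, or `"prior_draw"` (draw every block from its prior; with the
#'   very vague fixed-effect priors this can start chains at numerically
#'   extreme prevalences, hence not the default).
#' @return object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 2L, n_iter = 4000L, burn_in = 2000L,
                        thin = 2L, seed = 1L,
                        init = c("jitter", "zeros", "prior_draw")) {
  init <- match.arg(init)
  n_chains <- as.integer(n_chains); n_iter <- as.integer(n_iter)
  burn_in <- as.integer(burn_in); thin <- as.integer(thin)
  if (burn_in >= n_iter) stop("burn_in must be < n_iter")
  if (thin < 1L) stop("thin must be >= 1")
  if (n_chains < 1L) stop("need at least one chain")
  structure(
    list(n_chains = n_chains, n_iter = n_iter, burn_in = burn_in,
         thin = thin, seed = as.integer(seed), init = init),
    class = "mcmc_config"
  )
}

#' @rdname mcmc_config
#' @export
mcmc_config_full <- function(seed = 1L) {
  mcmc_config(n_chains = 2L, n_iter = 100000L, burn_in = 50000L,
              thin = 10L, seed = seed)
}

#' @rdname mcmc_config
#' @export
mcmc_config_desk <- function(seed = 1L, ...) {
  mcmc_config(n_chains = 2L, n_iter = 4000L, burn_in = 2000L, thin = 2L,
              seed = seed, ...)
}

# Column names of the flattened draw matrix, matching the C++ layout.
draw_names <- function(spec, N, K, T_, cov_names) {
  C <- length(cov_names)
  if (spec$model == "bym") {
    c("alpha0",
      sprintf("a[%d]", seq_len(K)),
      sprintf("u[%d]", seq_len(N)),
      sprintf("s[%d]", seq_len(N)),
      sprintf("b[%d,%d]", rep(seq_len(N), K), rep(seq_len(K), each = N)),
      if (C) paste0("beta_", cov_names),
      "tau_u", "tau_s",
      sprintf("Gamma[%d,%d]", rep(seq_len(K), K), rep(seq_len(K), each = K)))
  } else {
    c(sprintf("alpha[%d]", 1:2),
      sprintf("a[%d,%d]", rep(1:2, each = K), rep(seq_len(K), 2)),
      sprintf("b0[%d]", seq_len(N)),
      sprintf("bs[%d,%d]", rep(seq_len(N), K), rep(seq_len(K), each = N)),
      sprintf("bg[%d,%d]", rep(1:2, each = N), rep(seq_len(N), 2)),
      sprintf("rs[%d,%d,%d]", rep(1:2, each = N * K),
              rep(rep(seq_len(N), K), 2), rep(rep(seq_len(K), each = N), 2)),
      sprintf("beta[%d,%d]", rep(seq_len(N), T_), rep(seq_len(T_), each = N)),
      sprintf("log_delta[%d]", seq_len(T_)),
      if (C) paste0("beta_", rep(cov_names, 2), rep(c("_m", "_f"), each = C)),
      "tau_beta", "tau_b",
      sprintf("Gamma_b[%d,%d]", rep(seq_len(K), K), rep(seq_len(K), each = K)))
  }
}

scm_term_defaults <- function(spec) {
  list(shared_spatial = has_term(spec, "shared_spatial"),
       shared_spline = has_term(spec, "shared_spline"),
       gender_spline_fixed = has_term(spec, "gender_spline_fixed"),
       gender_spatial = has_term(spec, "gender_spatial"),
       gender_spline_random = has_term(spec, "gender_spline_random"),
       interaction = has_term(spec, "interaction"),
       delta_weights = has_term(spec, "delta_weights"))
}

bym_term_defaults <- function(spec) {
  list(fixed_spline = has_term(spec, "fixed_spline"),
       unstructured = has_term(spec, "unstructured"),
       spatial = has_term(spec, "spatial"),
       random_spline = has_term(spec, "random_spline"))
}

prior_for_cpp <- function(prior, K) {
  wd <- wishart_defaults(prior, K)
  list(fixed_effect_var = prior$fixed_effect_var,
       tau_shape = prior$tau_shape, tau_rate = prior$tau_rate,
       log_delta_var = prior$log_delta_var,
       precision_variant = match(prior$precision_prior,
                                 c("gamma_prec", "unif_sd",
                                   "halfnormal_var")),
       wishart_df = wd$df, wishart_R = wd$R)
}

# Initial state for one chain, drawn with the current RNG stream. The
# default "jitter" mode starts from crude empirical logits (pooled
# intercept, least-squares trend, halved region residuals) plus per-chain
# noise -- the standard way to start chains inside the typical set and
# avoid the slow escape from the precision-prior funnel; "zeros" and
# "prior_draw" are available for robustness checks.
make_init <- function(spec, data, basis, prior, mode, C) {
  N <- data$graph$n_regions; K <- basis$K; T_ <- length(data$waves)
  jit <- function(dims, on, sd = 0.1) {
    x <- array(0, dims)
    if (on && mode != "zeros") x[] <- stats::rnorm(length(x), 0, sd)
    x
  }
  center_cols <- function(m) sweep(m, 2L, colMeans(m))
  crude <- function(O, n) {
    # empirical logits with continuity correction
    alpha <- stats::qlogis((sum(O) + 0.5) / (sum(n) + 1))
    trend <- stats::qlogis((colSums(O) + 0.5) / (colSums(n) + 1)) - alpha
    region <- stats::qlogis((rowSums(O) + 0.5) / (rowSums(n) + 1)) - alpha
    list(alpha = alpha, a = stats::coef(stats::lm.fit(basis$B, trend)),
         region = region - mean(region))
  }
  noise <- function(x, sd = 0.05) x + stats::rnorm(length(x), 0, sd)
  if (spec$model == "bym") {
    terms <- bym_term_defaults(spec)
    cr <- crude(matrix(data$O[1L, , ], N, T_), matrix(data$n[1L, , ], N, T_))
    tau0 <- if (mode == "prior_draw") {
      stats::rgamma(2, prior$tau_shape, prior$tau_rate)
    } else pmax(2 / stats::var(c(cr$region / 2, 0.1, -0.1)), 10)
    tau0 <- rep(tau0, length.out = 2L)
    use_data <- mode == "jitter"
    half <- if (use_data) cr$region / 2 else numeric(N)
    u0 <- if (terms$unstructured) noise(half) else numeric(N)
    s0 <- if (terms$spatial) noise(half) else numeric(N)
    s0 <- s0 - mean(s0); if (terms$unstructured) u0 <- u0 - mean(u0)
    b0 <- jit(c(N, K), terms$random_spline, 0.05)
    if (terms$random_spline) b0 <- center_cols(b0)
    list(alpha0 = if (use_data) noise(cr$alpha) else
           if (mode == "zeros") 0 else stats::rnorm(1, 0, 0.1),
         a = if (use_data && has_term(spec, "fixed_spline"))
           noise(cr$a) else as.numeric(jit(K, terms$fixed_spline)),
         u0 = as.numeric(u0), s0 = as.numeric(s0), b_spline = b0,
         beta_cov = as.numeric(jit(max(C, 0L), C > 0L)),
         tau_u = tau0[1L], tau_s = tau0[2L], Gamma = diag(K))
  } else {
    terms <- scm_term_defaults(spec)
    cr1 <- crude(matrix(data$O[1L, , ], N, T_), matrix(data$n[1L, , ], N, T_))
    cr2 <- crude(matrix(data$O[2L, , ], N, T_), matrix(data$n[2L, , ], N, T_))
    tau0 <- if (mode == "prior_draw") {
      stats::rgamma(2, prior$tau_shape, prior$tau_rate)
    } else c(100, 100)
    use_data <- mode == "jitter"
    b0v <- (cr1$region + cr2$region) / 2
    bs <- jit(c(N, K), terms$shared_spline, 0.05)
    if (terms$shared_spline) bs <- center_cols(bs)
    rs <- array(0, c(N, K, 2))
    if (terms$gender_spline_random && mode != "zeros") {
      for (j in 1:2) rs[, , j] <- center_cols(jit(c(N, K), TRUE, 0.05))
    }
    bt <- jit(c(N, T_), terms$interaction, 0.05)
    if (terms$interaction) bt <- center_cols(bt)
    alpha_init <- if (use_data) noise(c(cr1$alpha, cr2$alpha)) else
      if (mode == "zeros") c(0, 0) else stats::rnorm(2, 0, 0.1)
    ag_init <- if (use_data && terms$gender_spline_fixed) {
      rbind(noise(cr1$a), noise(cr2$a))
    } else matrix(jit(c(2, K), terms$gender_spline_fixed), 2, K)
    bg_init <- if (use_data && terms$gender_spatial) {
      rbind(noise(cr1$region - b0v), noise(cr2$region - b0v))
    } else matrix(jit(c(2, N), terms$gender_spatial), 2, N)
    if (terms$gender_spatial) bg_init <- bg_init - rowMeans(bg_init)
    list(alpha = alpha_init, a_gender = ag_init,
         b0 = if (use_data && terms$shared_spatial) as.numeric(noise(b0v))
              else as.numeric(jit(N, terms$shared_spatial)),
         b_shared_spline = bs, b_gender = bg_init,
         beta_gender_spline = rs, beta_it = bt,
         log_delta = as.numeric(jit(T_, terms$delta_weights, 0.05)),
         beta_cov = matrix(jit(c(2, max(C, 0L)), C > 0L), 2),
         tau_beta = tau0[1L], tau_b = tau0[2L], Gamma_b = diag(K))
  }
}

panel_fingerprint <- function(data) {
  paste(data$graph$n_regions, length(data$waves), data$n_sexes,
        sum(data$O), sum(data$n), sum(data$O * seq_along(data$O)),
        paste(data$graph$region_ids, collapse = "|"), sep = ":")
}

#' Fit a spatio-temporal model by MCMC
#'
#' Runs the adaptive Metropolis-within-Gibbs sampler for the model named in
#' `spec` on a prevalence panel. Proposal scales adapt during burn-in only;
#' precisions with gamma priors and the MCAR precision matrix are updated by
#' conjugate Gibbs steps; intrinsic CAR blocks are recentred to sum to zero
#' on every sweep. For a fixed `mcmc$seed` the draws are bit-reproducible.
#'
#' @param spec a [model_spec()]; must match the panel (`"bym"` needs one
#'   sex, `"scm"` two).
#' @param data a [panel_counts()].
#' @param basis a [build_basis()] result on the panel's waves.
#' @param prior a [prior_config()].
#' @param mcmc a [mcmc_config()].
#' @return object of class `st_fit`: list with `draws` (list of
#'   chains x kept-draws matrices, named columns), `deviance` (list of
#'   per-chain vectors), `dic` (named vector `Dbar`, `pD`, `DIC`), `rhat`
#'   (per-parameter split-chain statistic), plus the spec, basis, prior,
#'   mcmc config, covariate design names and a data fingerprint.
#' @export
run_mcmc <- function(spec, data, basis, prior = prior_config(),
                     mcmc = mcmc_config()) {
  stopifnot(inherits(spec, "model_spec"), inherits(data, "panel_counts"),
            inherits(basis, "spline_basis"), inherits(prior, "prior_config"),
            inherits(mcmc, "mcmc_config"))
  if (spec$model == "bym" && data$n_sexes != 1L) {
    stop("BYM fits one sex at a time; use panel_one_sex()")
  }
  if (spec$model == "scm" && data$n_sexes != 2L) {
    stop("SCM needs a two-sex panel")
  }
  if (!identical(as.numeric(basis$waves), as.numeric(data$waves))) {
    stop("basis waves do not match panel waves")
  }
  N <- data$graph$n_regions; K <- basis$K; T_ <- length(data$waves)
  uses_car <- (spec$model == "bym" &&
                 any(c("spatial", "random_spline") %in% spec$terms)) ||
    (spec$model == "scm" &&
       any(c("shared_spline", "gender_spline_random", "interaction") %in%
             spec$terms))
  if (uses_car) validate_car_graph(data$graph)
  X <- covariate_design(spec, data, basis)
  if (spec$covariate_mode != "none" && length(X) == 0L) {
    stop("covariate_mode is '", spec$covariate_mode,
         "' but the panel has no covariates")
  }
  edges0 <- which(upper.tri(data$graph$W) & data$graph$W == 1L,
                  arr.ind = TRUE) - 1L
  storage.mode(edges0) <- "integer"
  cpp_prior <- prior_for_cpp(prior, K)
  terms <- if (spec$model == "bym") bym_term_defaults(spec)
           else scm_term_defaults(spec)
  nm <- draw_names(spec, N, K, T_, names(X))

  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  chains <- vector("list", mcmc$n_chains)
  devs <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    set.seed(mcmc$seed + 7919L * (ch - 1L))
    init <- make_init(spec, data, basis, prior, mcmc$init, length(X))
    slab <- function(x, j) matrix(x[j, , ], N, T_)
    res <- if (spec$model == "bym") {
      bym_sampler_cpp(slab(data$O, 1L), slab(data$n, 1L), basis$B, edges0,
                      X, init, cpp_prior, terms, mcmc$n_iter, mcmc$burn_in,
                      mcmc$thin)
    } else {
      scm_sampler_cpp(slab(data$O, 1L), slab(data$n, 1L),
                      slab(data$O, 2L), slab(data$n, 2L), basis$B, edges0, X,
                      init, cpp_prior, terms, mcmc$n_iter, mcmc$burn_in,
                      mcmc$thin)
    }
    dm <- res$draws
    colnames(dm) <- nm
    chains[[ch]] <- dm
    devs[[ch]] <- as.numeric(res$deviance)
    if (!all(is.finite(devs[[ch]]))) {
      stop("non-finite deviance encountered in chain ", ch)
    }
  }
  fit <- structure(
    list(model_spec = spec, draws = chains, deviance = devs,
         basis = basis, prior = prior, mcmc = mcmc,
         cov_names = names(X), sexes = data$sexes,
         region_ids = data$graph$region_ids, waves = data$waves,
         data_fingerprint = panel_fingerprint(data),
         model_tag = spec$model),
    class = "st_fit"
  )
  fit$rhat <- if (mcmc$n_chains >= 2L) gelman_rubin(fit$draws) else
    stats::setNames(rep(NA_real_, ncol(chains[[1L]])),
                    colnames(chains[[1L]]))
  if (spec$model == "bym" && mcmc$n_chains >= 2L) {
    # the convolution u + s is the identified spatial quantity; its
    # components are reported but convergence is tracked on the sum
    ucols <- sprintf("u[%d]", seq_len(N)); scols <- sprintf("s[%d]", seq_len(N))
    dchains <- lapply(fit$draws, function(ch) {
      conv <- ch[, ucols, drop = FALSE] + ch[, scols, drop = FALSE]
      colnames(conv) <- sprintf("conv[%d]", seq_len(N))
      conv
    })
    fit$rhat <- c(fit$rhat, gelman_rubin(dchains))
  }
  fit$dic <- compute_dic(fit, spec, data, basis)
  fit
}

#' @export
print.st_fit <- function(x, ...) {
  kept <- sum(vapply(x$draws, nrow, 1L))
  cat("<st_fit> ", toupper(x$model_spec$model), ", ",
      length(x$draws), " chains x ", nrow(x$draws[[1L]]), " kept draws (",
      kept, " total), DIC = ", round(x$dic[["DIC"]], 1),
      " (pD = ", round(x$dic[["pD"]], 1), ")\n", sep = "")
  invisible(x)
}

#' Pooled draw matrix of a fit
#'
#' @param fit an `st_fit`.
#' @return all chains row-bound into one matrix.
#' @export
pooled_draws <- function(fit) {
  do.call(rbind, fit$draws)
}

# Rebuild a params object from one flattened draw vector (or posterior
# means) using the C++/draw_names layout.
draws_to_params <- function(spec, v, N, K, T_, cov_names) {
  C <- length(cov_names)
  if (spec$model == "bym") {
    g <- function(nm) unname(v[nm])
    bym_params(
      alpha0 = g("alpha0"),
      a = g(sprintf("a[%d]", seq_len(K))),
      u0 = g(sprintf("u[%d]", seq_len(N))),
      s0 = g(sprintf("s[%d]", seq_len(N))),
      b_spline = matrix(g(sprintf("b[%d,%d]", rep(seq_len(N), K),
                                  rep(seq_len(K), each = N))), N, K),
      tau_u = g("tau_u"), tau_s = g("tau_s"),
      Gamma = matrix(g(sprintf("Gamma[%d,%d]", rep(seq_len(K), K),
                               rep(seq_len(K), each = K))), K, K),
      beta_cov = if (C) stats::setNames(g(paste0("beta_", cov_names)),
                                        cov_names)
    )
  } else {
    g <- function(nm) unname(v[nm])
    rs <- array(0, c(2, N, K))
    for (j in 1:2) {
      rs[j, , ] <- matrix(g(sprintf("rs[%d,%d,%d]", j,
                                    rep(seq_len(N), K),
                                    rep(seq_len(K), each = N))), N, K)
    }
    bc <- NULL
    if (C) {
      bc <- rbind(g(paste0("beta_", cov_names, "_m")),
                  g(paste0("beta_", cov_names, "_f")))
      colnames(bc) <- cov_names
    }
    scm_params(
      alpha = g(sprintf("alpha[%d]", 1:2)),
      a_gender = matrix(g(sprintf("a[%d,%d]", rep(1:2, each = K),
                                  rep(seq_len(K), 2))), 2, K, byrow = TRUE),
      b0 = g(sprintf("b0[%d]", seq_len(N))),
      b_shared_spline = matrix(g(sprintf("bs[%d,%d]", rep(seq_len(N), K),
                                         rep(seq_len(K), each = N))), N, K),
      b_gender = matrix(g(sprintf("bg[%d,%d]", rep(1:2, each = N),
                                  rep(seq_len(N), 2))), 2, N, byrow = TRUE),
      beta_gender_spline = rs,
      beta_it = matrix(g(sprintf("beta[%d,%d]", rep(seq_len(N), T_),
                                 rep(seq_len(T_), each = N))), N, T_),
      log_delta = g(sprintf("log_delta[%d]", seq_len(T_))),
      tau_beta = g("tau_beta"), tau_b = g("tau_b"),
      Gamma_b = matrix(g(sprintf("Gamma_b[%d,%d]", rep(seq_len(K), K),
                                 rep(seq_len(K), each = K))), K, K),
      beta_cov = bc
    )
  }
}
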