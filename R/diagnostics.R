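#' Split-chain Brooks-Gelman-Rubin diagnostic
#'
#' Potential scale reduction factor computed after splitting every chain in
#' half (so within-chain drift also registers). Values near 1 indicate that
#' the between-chain variance matches the within-chain variance; the usual
#' convergence gate in this package is 1.1. Parameters with zero variance
#' everywhere (e.g. blocks disabled in the model spec) report 1.
#'
#' @param draws list of draw matrices (chains), identical named columns, or
#'   an `st_fit`.
#' @return named numeric vector of R-hat values, one per parameter.
#' @export
gelman_rubin <- function(draws) {
  if (inherits(draws, "st_fit")) draws <- draws$draws
  if (!is.list(draws) || length(draws) < 2L) {
    stop("Brooks-Gelman-Rubin needs at least 2 chains")
  }
  n <- nrow(draws[[1L]])
  if (n < 10L) stop("need at least 10 draws per chain")
  half <- n %/% 2L
  splits <- list()
  for (ch in draws) {
    splits[[length(splits) + 1L]] <- ch[seq_len(half), , drop = FALSE]
    splits[[length(splits) + 1L]] <- ch[(half + 1L):(2L * half), ,
                                        drop = FALSE]
  }
  m <- length(splits)
  nn <- half
  means <- vapply(splits, colMeans, numeric(ncol(draws[[1L]])))
  vars <- vapply(splits, function(s) apply(s, 2L, stats::var),
                 numeric(ncol(draws[[1L]])))
  if (is.null(dim(means))) {    # single-parameter edge case
    means <- matrix(means, nrow = 1L)
    vars <- matrix(vars, nrow = 1L)
  }
  W <- rowMeans(vars)
  B <- nn * apply(means, 1L, stats::var)
  vhat <- (nn - 1) / nn * W + B / nn
  rhat <- sqrt(vhat / W)
  rhat[W == 0 & B == 0] <- 1
  stats::setNames(rhat, colnames(draws[[1L]]))
}

#' Within-chain autocorrelation of MCMC draws
#'
#' Standard sample autocorrelation per parameter, averaged across chains;
#' lag 0 is identically 1. Constant (disabled) parameters report 0 beyond
#' lag 0.
#'
#' @param draws list of chain matrices, an `st_fit`, or a single numeric
#'   vector.
#' @param max_lag largest lag (default 20); must be below the chain length.
#' @return matrix with `max_lag + 1` rows (lags 0..max_lag) and one column
#'   per parameter.
#' @export
autocorrelation <- function(draws, max_lag = 20L) {
  if (inherits(draws, "st_fit")) draws <- draws$draws
  if (is.numeric(draws) && is.null(dim(draws))) {
    draws <- list(matrix(draws, ncol = 1L,
                         dimnames = list(NULL, "param")))
  }
  if (is.matrix(draws)) draws <- list(draws)
  n <- nrow(draws[[1L]])
  if (n <= max_lag) stop("max_lag must be below the chain length")
  per_chain <- lapply(draws, function(ch) {
    apply(ch, 2L, function(x) {
      if (stats::var(x) == 0) {
        c(1, rep(0, max_lag))
      } else {
        drop(stats::acf(x, lag.max = max_lag, plot = FALSE,
                        demean = TRUE)$acf)
      }
    })
  })
  out <- Reduce(`+`, per_chain) / length(per_chain)
  rownames(out) <- paste0("lag", 0:max_lag)
  out
}

#' Deviance information criterion of a fit
#'
#' `Dbar` is the posterior mean of the deviance trace recorded at every
#' kept draw; `D(theta-bar)` is the deviance at the posterior mean of the
#' linear-predictor parameters (the classic plug-in convention); then
#' `pD = Dbar - D(theta-bar)` and `DIC = Dbar + pD`. `D(theta-bar)` is
#' evaluated in R from the pure-R linear predictors, which doubles as a
#' cross-check of the C++ likelihood bookkeeping.
#'
#' @param fit an `st_fit`.
#' @param spec,data,basis the model spec, panel and basis of the fit
#'   (defaults taken from the fit where stored).
#' @return named vector `c(Dbar, pD, DIC)`.
#' @export
compute_dic <- function(fit, spec = fit$model_spec, data, basis = fit$basis) {
  stopifnot(inherits(fit, "st_fit"))
  devs <- unlist(fit$deviance)
  if (length(devs) == 0L) stop("empty deviance trace")
  dbar <- mean(devs)
  theta_bar <- colMeans(pooled_draws(fit))
  N <- length(fit$region_ids); K <- basis$K; T_ <- length(fit$waves)
  params <- draws_to_params(spec, theta_bar, N, K, T_, fit$cov_names)
  dhat <- deviance_at(params, spec, data, basis)
  pd <- dbar - dhat
  c(Dbar = dbar, pD = pd, DIC = dbar + pd)
}

# -2 log-likelihood at a single parameter set, via the R-level predictors.
deviance_at <- function(params, spec, data, basis) {
  X <- covariate_design(spec, data, basis)
  if (spec$model == "bym") {
    eta <- bym_linear_predictor(params, basis, X)
    -2 * binom_loglik(data$O[1L, , ], data$n[1L, , ], eta)
  } else {
    lp <- scm_linear_predictor(params, basis, X)
    -2 * (binom_loglik(data$O[1L, , ], data$n[1L, , ], lp[1L, , ]) +
            binom_loglik(data$O[2L, , ], data$n[2L, , ], lp[2L, , ]))
  }
}
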