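#' Covariate design used by the samplers and predictors
#'
#' Builds the named list of `N x T` design matrices implied by the
#' covariate mode. `"constant"` passes the regional covariates through
#' unchanged (one coefficient each); `"time_varying"` multiplies each
#' covariate by every fixed-spline basis column, so each covariate gets K
#' coefficients and its effect varies smoothly over time.
#'
#' @param spec a [model_spec()].
#' @param data a [panel_counts()].
#' @param basis a [build_basis()] result.
#' @return named list of `N x T` matrices (empty list for mode `"none"` or
#'   when the panel carries no covariates).
#' @export
covariate_design <- function(spec, data, basis) {
  if (spec$covariate_mode == "none" || is.null(data$covariates)) {
    return(list())
  }
  if (spec$covariate_mode == "constant") return(data$covariates)
  out <- list()
  for (nm in names(data$covariates)) {
    X <- data$covariates[[nm]]
    # base column keeps the constant effect nested (the intercept-dropped
    # basis vanishes at the first wave, so without it a constant effect
    # could not be represented)
    out[[paste0(nm, ".B0")]] <- X
    for (k in seq_len(basis$K)) {
      # row i, column t design: x_it * B_k(t)
      out[[paste0(nm, ".B", k)]] <- sweep(X, 2L, basis$B[, k], `*`)
    }
  }
  out
}

covariate_design_names <- function(spec, data, basis) {
  names(covariate_design(spec, data, basis))
}

cov_contribution <- function(design, coef) {
  if (length(design) == 0L || is.null(coef)) return(0)
  if (length(coef) != length(design)) {
    stop("covariate coefficient length ", length(coef),
         " does not match design length ", length(design))
  }
  Reduce(`+`, Map(`*`, design, as.numeric(coef)))
}

#' Linear predictor of the spatio-temporal BYM model
#'
#' `logit(p_it) = alpha0 + sum_k a_k B_k(t) + u_i0 + s_i0 +
#' sum_k b_ik B_k(t) [+ covariates]`.
#'
#' @param params a [bym_params()].
#' @param basis a [build_basis()] result.
#' @param X optional named list of `N x T` covariate design matrices
#'   matching `params$beta_cov`.
#' @param prevalence if `TRUE` return `plogis` of the predictor instead.
#' @return `N x T` matrix of logits (or prevalences).
#' @export
bym_linear_predictor <- function(params, basis, X = NULL,
                                 prevalence = FALSE) {
  stopifnot(inherits(params, "bym_params"), inherits(basis, "spline_basis"))
  B <- basis$B; K <- basis$K; T_ <- nrow(B)
  N <- max(length(params$u0), length(params$s0), nrow(params$b_spline), 1L)
  eta <- matrix(params$alpha0, N, T_)
  if (length(params$a)) {
    if (length(params$a) != K) {
      stop("a has length ", length(params$a), " but basis has K = ", K)
    }
    eta <- eta + matrix(B %*% params$a, N, T_, byrow = TRUE)
  }
  if (length(params$u0)) {
    if (length(params$u0) != N) stop("u0 has wrong length (region axis)")
    eta <- eta + params$u0
  }
  if (length(params$s0)) {
    if (length(params$s0) != N) stop("s0 has wrong length (region axis)")
    eta <- eta + params$s0
  }
  if (!is.null(params$b_spline)) {
    if (!identical(dim(params$b_spline), c(N, K))) {
      stop("b_spline must be N x K = ", N, " x ", K)
    }
    eta <- eta + params$b_spline %*% t(B)
  }
  eta <- eta + cov_contribution(X, params$beta_cov)
  if (prevalence) stats::plogis(eta) else eta
}

#' Linear predictors of the spatio-temporal shared component model
#'
#' Per sex j: `logit(p_jit) = alpha_j + eta_jit` with
#' `eta_1it = (b_0i + RS_0i(t)) * delta_t + S_1(t) + b_1i + RS_1i(t) +
#' beta_it` and the shared term divided by `delta_t` for j = 2. The
#' spatio-temporal interaction `beta_it` enters both sexes.
#'
#' @param params a [scm_params()].
#' @param basis a [build_basis()] result.
#' @param X optional named list of `N x T` covariate design matrices.
#' @param prevalence if `TRUE` return prevalences.
#' @return `2 x N x T` array of logits (or prevalences).
#' @export
scm_linear_predictor <- function(params, basis, X = NULL,
                                 prevalence = FALSE) {
  stopifnot(inherits(params, "scm_params"), inherits(basis, "spline_basis"))
  comps <- scm_predictor_components(params, basis, X)
  out <- array(NA_real_, c(2L, dim(comps$eta1)))
  out[1L, , ] <- params$alpha[1L] + comps$eta1
  out[2L, , ] <- params$alpha[2L] + comps$eta2
  if (prevalence) stats::plogis(out) else out
}

# Internal: the eta_jit surfaces (without alpha_j) plus the weighted shared
# terms, shared by the predictor, the simulator and variance_share().
scm_predictor_components <- function(params, basis, X = NULL) {
  B <- basis$B; K <- basis$K; T_ <- nrow(B)
  N <- max(length(params$b0), nrow(params$b_shared_spline),
           NROW(params$beta_it), ncol(params$b_gender), 1L)
  zero <- matrix(0, N, T_)
  shared <- zero
  if (length(params$b0)) {
    if (length(params$b0) != N) stop("b0 has wrong length (region axis)")
    shared <- shared + params$b0
  }
  if (!is.null(params$b_shared_spline)) {
    if (!identical(dim(params$b_shared_spline), c(N, K))) {
      stop("b_shared_spline must be N x K = ", N, " x ", K)
    }
    shared <- shared + params$b_shared_spline %*% t(B)
  }
  delta <- if (length(params$log_delta)) {
    if (length(params$log_delta) != T_) {
      stop("log_delta must have length T = ", T_)
    }
    exp(params$log_delta)
  } else rep(1, T_)
  shared1 <- sweep(shared, 2L, delta, `*`)
  shared2 <- sweep(shared, 2L, delta, `/`)
  gender <- function(j) {
    g <- zero
    if (!is.null(params$a_gender)) {
      if (!identical(dim(params$a_gender), c(2L, K))) {
        stop("a_gender must be 2 x K = 2 x ", K)
      }
      g <- g + matrix(B %*% params$a_gender[j, ], N, T_, byrow = TRUE)
    }
    if (!is.null(params$b_gender)) {
      if (!identical(dim(params$b_gender), c(2L, N))) {
        stop("b_gender must be 2 x N = 2 x ", N)
      }
      g <- g + params$b_gender[j, ]
    }
    if (!is.null(params$beta_gender_spline)) {
      if (!identical(dim(params$beta_gender_spline), c(2L, N, K))) {
        stop("beta_gender_spline must be 2 x N x K")
      }
      g <- g + matrix(params$beta_gender_spline[j, , ], N, K) %*% t(B)
    }
    g
  }
  inter <- if (!is.null(params$beta_it)) {
    if (!identical(dim(params$beta_it), c(N, T_))) {
      stop("beta_it must be N x T = ", N, " x ", T_)
    }
    params$beta_it
  } else zero
  covar <- cov_gender_contribution(X, params$beta_cov, zero)
  list(
    shared1 = shared1, shared2 = shared2, delta = delta,
    eta1 = shared1 + gender(1L) + inter + covar[[1L]],
    eta2 = shared2 + gender(2L) + inter + covar[[2L]]
  )
}

cov_gender_contribution <- function(X, beta_cov, zero) {
  if (length(X) == 0L || is.null(beta_cov)) return(list(zero, zero))
  if (!is.matrix(beta_cov) || nrow(beta_cov) != 2L ||
      ncol(beta_cov) != length(X)) {
    stop("beta_cov must be a 2 x ", length(X), " matrix for the SCM")
  }
  lapply(1:2, function(j) cov_contribution(X, beta_cov[j, ]))
}
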