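#' Parameter set for the spatio-temporal BYM model
#'
#' Collects every unknown of the single-outcome model
#' `logit(p_it) = alpha0 + S0(t) + u_i0 + s_i0 + RS_i(t)` with
#' `S0(t) = sum_k a_k B_k(t)` and `RS_i(t) = sum_k b_ik B_k(t)`.
#'
#' @param alpha0 scalar intercept.
#' @param a length-K fixed spline coefficients.
#' @param u0 length-N unstructured region effects.
#' @param s0 length-N ICAR spatial effects (sum-to-zero).
#' @param b_spline N x K random spline coefficients (columns sum-to-zero).
#' @param tau_u,tau_s positive precisions of `u0` and `s0`.
#' @param Gamma K x K symmetric positive-definite MCAR precision.
#' @param beta_cov optional named covariate coefficients.
#' @return object of class `bym_params`.
#' @export
bym_params <- function(alpha0 = 0, a = numeric(0), u0 = numeric(0),
                       s0 = numeric(0), b_spline = NULL,
                       tau_u = 1, tau_s = 1, Gamma = NULL,
                       beta_cov = NULL) {
  p <- structure(
    list(alpha0 = as.numeric(alpha0), a = as.numeric(a),
         u0 = as.numeric(u0), s0 = as.numeric(s0),
         b_spline = b_spline, tau_u = tau_u, tau_s = tau_s,
         Gamma = Gamma, beta_cov = beta_cov),
    class = "bym_params"
  )
  if (length(p$alpha0) != 1L) stop("alpha0 must be scalar")
  if (tau_u <= 0 || tau_s <= 0) stop("precisions must be positive")
  if (!is.null(Gamma)) check_spd(Gamma, "Gamma")
  p
}

#' Parameter set for the spatio-temporal shared component model
#'
#' Collects every unknown of the two-outcome model (j = 1 males, j = 2
#' females):
#' `logit(p_1it) = alpha_1 + (b_0i + RS_0i(t)) * delta_t + S_1(t) + b_1i +
#' RS_1i(t) + beta_it` and symmetrically with `1/delta_t` for j = 2.
#'
#' @param alpha length-2 intercepts.
#' @param a_gender 2 x K fixed spline coefficients.
#' @param b0 length-N shared spatial effects.
#' @param b_shared_spline N x K shared random spline coefficients (columns
#'   sum-to-zero).
#' @param b_gender 2 x N gender-specific spatial effects.
#' @param beta_gender_spline 2 x N x K gender-specific random spline
#'   coefficients.
#' @param beta_it N x T spatio-temporal interaction (columns sum-to-zero).
#' @param log_delta length-T log shared weights.
#' @param tau_beta,tau_b positive precisions of `beta_it` and of the
#'   gender-specific spline CARs.
#' @param Gamma_b K x K SPD precision of the shared-spline MCAR.
#' @param beta_cov optional 2 x C matrix of covariate coefficients (row per
#'   sex, named columns).
#' @return object of class `scm_params`.
#' @export
scm_params <- function(alpha = c(0, 0), a_gender = NULL, b0 = numeric(0),
                       b_shared_spline = NULL, b_gender = NULL,
                       beta_gender_spline = NULL, beta_it = NULL,
                       log_delta = numeric(0), tau_beta = 1, tau_b = 1,
                       Gamma_b = NULL, beta_cov = NULL) {
  if (length(alpha) != 2L) stop("alpha must have length 2")
  if (tau_beta <= 0 || tau_b <= 0) stop("precisions must be positive")
  if (!is.null(Gamma_b)) check_spd(Gamma_b, "Gamma_b")
  structure(
    list(alpha = as.numeric(alpha), a_gender = a_gender,
         b0 = as.numeric(b0), b_shared_spline = b_shared_spline,
         b_gender = b_gender, beta_gender_spline = beta_gender_spline,
         beta_it = beta_it, log_delta = as.numeric(log_delta),
         tau_beta = tau_beta, tau_b = tau_b, Gamma_b = Gamma_b,
         beta_cov = beta_cov),
    class = "scm_params"
  )
}

check_spd <- function(M, what) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) stop(what, " must be square")
  if (max(abs(M - t(M))) > 1e-8) stop(what, " must be symmetric")
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop(what, " must be positive definite")
  invisible(M)
}

#' Zero-initialised parameter sets of the right shape
#'
#' @param spec a [model_spec()].
#' @param data a [panel_counts()].
#' @param basis a [build_basis()] result.
#' @return a [bym_params()] or [scm_params()] with all effects zero,
#'   precisions 1 and MCAR precision the identity.
#' @export
zero_params <- function(spec, data, basis) {
  N <- data$graph$n_regions; K <- basis$K; T_ <- length(data$waves)
  cov_names <- covariate_design_names(spec, data, basis)
  if (spec$model == "bym") {
    bym_params(
      alpha0 = 0, a = numeric(K), u0 = numeric(N), s0 = numeric(N),
      b_spline = matrix(0, N, K), tau_u = 1, tau_s = 1, Gamma = diag(K),
      beta_cov = if (length(cov_names))
        stats::setNames(numeric(length(cov_names)), cov_names)
    )
  } else {
    scm_params(
      alpha = c(0, 0), a_gender = matrix(0, 2, K), b0 = numeric(N),
      b_shared_spline = matrix(0, N, K), b_gender = matrix(0, 2, N),
      beta_gender_spline = array(0, c(2, N, K)),
      beta_it = matrix(0, N, T_), log_delta = numeric(T_),
      tau_beta = 1, tau_b = 1, Gamma_b = diag(K),
      beta_cov = if (length(cov_names))
        matrix(0, 2, length(cov_names),
               dimnames = list(NULL, cov_names))
    )
  }
}
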