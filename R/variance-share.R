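#' Variance share of the shared component
#'
#' For one parameter set, the proportion of the across-region variance of
#' each sex's linear predictor `eta_jit` (intercept excluded) explained by
#' the weighted shared component:
#' `eta_1(t) = var_i((b_0i + RS_0i(t)) * delta_t) / var_i(eta_1it)` and
#' symmetrically with `1/delta_t` for sex 2. Variances are empirical across
#' regions (denominator N - 1). A ratio may exceed 1 when the shared and
#' gender-specific components are anticorrelated across regions; such cells
#' are flagged rather than clipped.
#'
#' @param params a [scm_params()].
#' @param basis a [build_basis()] result.
#' @param X optional covariate design (named list of `N x T` matrices).
#' @return `2 x T` matrix of shares with attribute `"flagged"`: logical
#'   `2 x T` matrix marking cells above `1 + 1e-9`.
#' @export
variance_share <- function(params, basis, X = NULL) {
  stopifnot(inherits(params, "scm_params"))
  comps <- scm_predictor_components(params, basis, X)
  N <- nrow(comps$eta1)
  if (N < 2L) stop("variance share needs at least 2 regions")
  T_ <- ncol(comps$eta1)
  share <- matrix(NA_real_, 2L, T_,
                  dimnames = list(c("m", "f"), colnames(comps$eta1)))
  num <- rbind(apply(comps$shared1, 2L, stats::var),
               apply(comps$shared2, 2L, stats::var))
  den <- rbind(apply(comps$eta1, 2L, stats::var),
               apply(comps$eta2, 2L, stats::var))
  share[] <- ifelse(num == 0, 0, num / den)
  attr(share, "flagged") <- share > 1 + 1e-9
  share
}
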