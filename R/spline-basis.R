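#' Centre calendar years
#'
#' Survey waves are unequally spaced, so the models work on calendar time
#' centred at a reference year (default 2004, the middle of the study
#' period) rather than on wave index.
#'
#' @param years integer (or numeric) calendar years.
#' @param center_year reference year subtracted from every element.
#' @return numeric vector `years - center_year`.
#' @examples
#' center_years(c(1991, 2004, 2015), 2004)
#' @export
center_years <- function(years, center_year = 2004) {
  if (length(years) == 0L) stop("years must be nonempty")
  as.numeric(years) - as.numeric(center_year)
}

#' Cubic B-spline basis for the temporal trend
#'
#' Builds the clamped cubic B-spline basis on centred calendar time. With
#' `L` interior knots the clamped basis has `L + 4` functions whose values
#' are nonnegative and sum to one at every time point; the first column is
#' then dropped so that the basis excludes an implicit intercept, leaving
#' `K = L + 3` columns. The model intercept is a separate parameter, so the
#' drop restores identifiability; dropping the *first* column is fixed by
#' convention for reproducibility.
#'
#' @param waves ordered vector of calendar years (the observation times).
#' @param interior_knots interior knot positions on the centred scale,
#'   strictly inside `(min, max)` of the centred waves. May be empty.
#' @param center_year passed to [center_years()].
#' @return An object of class `spline_basis`: list with `waves`,
#'   `center_year`, `t_values`, `interior_knots`, `degree` (3), `K`, and the
#'   `T x K` matrix `B`.
#' @examples
#' sb <- build_basis(c(1991, 1993, 1997, 2000, 2004, 2006, 2009, 2011, 2015),
#'                   interior_knots = 0)
#' sb$K  # L + 3 = 4
#' @export
build_basis <- function(waves, interior_knots = numeric(0),
                        center_year = 2004) {
  if (length(waves) < 2L) stop("need at least two waves")
  if (is.unsorted(waves, strictly = TRUE)) {
    stop("waves must be strictly increasing")
  }
  tv <- center_years(waves, center_year)
  interior_knots <- as.numeric(interior_knots)
  if (anyDuplicated(interior_knots)) stop("duplicate interior knots")
  interior_knots <- sort(interior_knots)
  lo <- min(tv); hi <- max(tv)
  if (length(interior_knots) &&
      (min(interior_knots) <= lo || max(interior_knots) >= hi)) {
    stop("interior knots must lie strictly inside (", lo, ", ", hi, ")")
  }
  full <- full_clamped_basis(tv, interior_knots, lo, hi)
  B <- full[, -1L, drop = FALSE]
  colnames(B) <- paste0("B", seq_len(ncol(B)))
  structure(
    list(waves = waves, center_year = center_year, t_values = tv,
         interior_knots = interior_knots, degree = 3L, K = ncol(B), B = B),
    class = "spline_basis"
  )
}

# Full clamped cubic basis (L + 4 columns, rows summing to 1) evaluated at x.
full_clamped_basis <- function(x, interior_knots, lo, hi) {
  knots <- c(rep(lo, 4L), interior_knots, rep(hi, 4L))
  # splineDesign is right-open at the last boundary knot; evaluate the
  # endpoint with outer.ok and fix the final row analytically: at the
  # clamped right boundary the last basis function equals 1.
  B <- splines::splineDesign(knots, x, ord = 4L, outer.ok = TRUE)
  at_hi <- which(x == hi)
  if (length(at_hi)) {
    B[at_hi, ] <- 0
    B[at_hi, ncol(B)] <- 1
  }
  B
}

#' @export
print.spline_basis <- function(x, ...) {
  cat("<spline_basis> cubic, ", length(x$waves), " waves, ",
      length(x$interior_knots), " interior knot(s), K = ", x$K, "\n", sep = "")
  invisible(x)
}

#' Evaluate the (intercept-dropped) basis at arbitrary times
#'
#' @param basis a [build_basis()] result.
#' @param t_new centred times within the clamped range.
#' @return matrix with `length(t_new)` rows and `basis$K` columns.
#' @export
eval_basis <- function(basis, t_new) {
  stopifnot(inherits(basis, "spline_basis"))
  lo <- min(basis$t_values); hi <- max(basis$t_values)
  if (any(t_new < lo | t_new > hi)) {
    stop("t_new outside the clamped range [", lo, ", ", hi, "]")
  }
  full <- full_clamped_basis(t_new, basis$interior_knots, lo, hi)
  full[, -1L, drop = FALSE]
}

#' DIC-guided forward selection of interior knots
#'
#' Starting from one knot at the centred reference year (position 0), each
#' step adds the candidate knot whose inclusion reduces DIC the most, and
#' stops when the best achievable reduction falls below
#' `dic_drop_threshold`. This is the forward-selection strategy for
#' regression-spline knots, with candidates defaulting to the centred
#' interior waves.
#'
#' @param data a [panel_counts()] object.
#' @param model_spec a [model_spec()].
#' @param candidate_knots candidate interior-knot positions (centred scale).
#' @param fit_fn function `(data, model_spec, knots) -> list` whose result
#'   contains a scalar `dic` element. Defaults to a desk-scale
#'   [run_mcmc()] fit via [fit_dic_fn()].
#' @param dic_drop_threshold minimum DIC reduction worth another knot
#'   (default 2, the conventional materiality threshold for DIC
#'   differences).
#' @param start_knots initial knot set (default 0, the centred reference
#'   year).
#' @return list with `knots` (chosen set, sorted), `trace` (data.frame of
#'   every evaluated knot set and its DIC), `dic` (DIC of the chosen set).
#' @export
forward_knot_selection <- function(data, model_spec,
                                   candidate_knots = NULL,
                                   fit_fn = NULL,
                                   dic_drop_threshold = 2,
                                   start_knots = 0) {
  stopifnot(inherits(data, "panel_counts"))
  if (is.null(candidate_knots)) {
    tv <- center_years(data$waves, 2004)
    candidate_knots <- tv[tv > min(tv) & tv < max(tv)]
  }
  if (is.null(fit_fn)) fit_fn <- fit_dic_fn()
  evaluate <- function(knots) {
    res <- tryCatch(fit_fn(data, model_spec, knots), error = function(e) {
      stop("fit failed for knot set {", paste(knots, collapse = ", "),
           "}: ", conditionMessage(e))
    })
    as.numeric(res$dic)
  }
  current <- sort(unique(as.numeric(start_knots)))
  trace <- data.frame(step = 0L,
                      knots = paste(current, collapse = ","),
                      dic = evaluate(current),
                      stringsAsFactors = FALSE)
  repeat {
    pool <- setdiff(candidate_knots, current)
    if (length(pool) == 0L) break
    if (is.infinite(dic_drop_threshold) && dic_drop_threshold > 0) break
    cur_dic <- trace$dic[nrow(trace)]
    cand_dic <- vapply(pool, function(k) evaluate(sort(c(current, k))),
                       numeric(1))
    best <- which.min(cand_dic)
    if (cur_dic - cand_dic[best] < dic_drop_threshold) break
    current <- sort(c(current, pool[best]))
    trace <- rbind(trace, data.frame(
      step = nrow(trace),
      knots = paste(current, collapse = ","),
      dic = cand_dic[best], stringsAsFactors = FALSE))
  }
  list(knots = current, trace = trace, dic = trace$dic[nrow(trace)])
}

#' Default DIC evaluator for knot selection
#'
#' Returns a `fit_fn` for [forward_knot_selection()] that fits the model by
#' [run_mcmc()] at the supplied MCMC settings and reports its DIC.
#'
#' @param mcmc a [mcmc_config()]; defaults to the desk-scale settings.
#' @param prior a [prior_config()].
#' @return function `(data, model_spec, knots) -> list(dic = ...)`.
#' @export
fit_dic_fn <- function(mcmc = mcmc_config(), prior = prior_config()) {
  function(data, model_spec, knots) {
    basis <- build_basis(data$waves, interior_knots = knots)
    fit <- run_mcmc(model_spec, data, basis, prior, mcmc)
    list(dic = fit$dic[["DIC"]], fit = fit)
  }
}
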