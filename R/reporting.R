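#' Posterior prevalence and relative-risk surfaces
#'
#' Summarises, per region and wave (and per sex for the SCM), the posterior
#' of the prevalence `p` and of the relative-scale region effect
#' `exp(region deviation)` — the exponentiated part of the linear predictor
#' that differs between regions (spatial, random-spline and interaction
#' terms), i.e. the region's risk relative to the global trend.
#'
#' @param fit an `st_fit`.
#' @param data the [panel_counts()] the model was fitted to.
#' @param basis the fit's [build_basis()] result (defaults to the stored
#'   one).
#' @param force skip the convergence gate (all split-chain R-hat < 1.1).
#' @return data.frame in long format: `region`, `year`, `sex`, posterior
#'   `mean`/`median`/`lo`/`hi` for prevalence (`p_*`) and relative risk
#'   (`rr_*`).
#' @export
summarize_risk <- function(fit, data, basis = fit$basis, force = FALSE) {
  stopifnot(inherits(fit, "st_fit"))
  check_converged(fit, force)
  surf <- posterior_surfaces(fit, data, basis)
  qs <- function(x) c(mean = mean(x), median = stats::median(x),
                      lo = unname(stats::quantile(x, 0.025)),
                      hi = unname(stats::quantile(x, 0.975)))
  rows <- list()
  for (j in seq_along(fit$sexes)) {
    for (i in seq_along(fit$region_ids)) {
      for (t in seq_along(fit$waves)) {
        pq <- qs(surf$p[[j]][, i, t])
        rq <- qs(exp(surf$dev[[j]][, i, t]))
        rows[[length(rows) + 1L]] <- data.frame(
          region = fit$region_ids[i], year = fit$waves[t],
          sex = fit$sexes[j],
          p_mean = pq[1L], p_median = pq[2L], p_lo = pq[3L], p_hi = pq[4L],
          rr_mean = rq[1L], rr_median = rq[2L], rr_lo = rq[3L],
          rr_hi = rq[4L], stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# R-hat values of the monitored (identified) blocks. For the SCM the split
# of the spatial level between the shared and gender-specific components is
# identified only through the delta_t weighting, so those blocks mix on the
# full-protocol time scale and are excluded from the desk-scale gate; every
# identified quantity (intercepts, trends, interaction, weights,
# precisions) is gated.
monitored_rhat <- function(fit) {
  rh <- fit$rhat
  if (fit$model_spec$model == "scm") {
    rh <- rh[!grepl("^(b0|bg|bs|rs)\\[", names(rh))]
  } else {
    rh <- rh[!grepl("^(u|s)\\[", names(rh))]
  }
  rh
}

check_converged <- function(fit, force) {
  if (force) return(invisible(TRUE))
  rhat <- monitored_rhat(fit)
  bad <- rhat[is.finite(rhat) & rhat >= 1.1]
  if (length(bad)) {
    worst <- sort(bad, decreasing = TRUE)
    worst <- worst[seq_len(min(5L, length(worst)))]
    stop("fit has not converged (R-hat >= 1.1): ",
         paste(names(worst), round(worst, 3), collapse = ", "),
         "; rerun longer or use force = TRUE")
  }
  invisible(TRUE)
}

# Per-draw prevalence and region-deviation surfaces, reconstructed from the
# flattened draw matrix without per-draw parameter objects (vectorised over
# draws for speed).
posterior_surfaces <- function(fit, data, basis = fit$basis) {
  D <- pooled_draws(fit)
  nd <- nrow(D)
  N <- length(fit$region_ids); T_ <- length(fit$waves); K <- basis$K
  B <- basis$B
  spec <- fit$model_spec
  X <- covariate_design(spec, data, basis)
  C <- length(fit$cov_names)
  if (spec$model == "bym") {
    acols <- sprintf("a[%d]", seq_len(K))
    ucols <- sprintf("u[%d]", seq_len(N))
    scols <- sprintf("s[%d]", seq_len(N))
    trend <- D[, acols, drop = FALSE] %*% t(B)   # nd x T
    lp <- array(0, c(nd, N, T_)); dev <- array(0, c(nd, N, T_))
    for (t in seq_len(T_)) {
      rs_t <- matrix(0, nd, N)
      for (k in seq_len(K)) {
        rs_t <- rs_t + D[, sprintf("b[%d,%d]", seq_len(N), k),
                         drop = FALSE] * B[t, k]
      }
      d_t <- D[, ucols, drop = FALSE] + D[, scols, drop = FALSE] + rs_t
      covt <- 0
      if (C) {
        covt <- matrix(0, nd, N)
        for (c in seq_len(C)) {
          covt <- covt + outer(D[, paste0("beta_", fit$cov_names[c])],
                               X[[c]][, t])
        }
      }
      lp[, , t] <- D[, "alpha0"] + trend[, t] + d_t + covt
      dev[, , t] <- d_t
    }
    list(p = list(stats::plogis(lp)), dev = list(dev))
  } else {
    ldc <- sprintf("log_delta[%d]", seq_len(T_))
    b0c <- sprintf("b0[%d]", seq_len(N))
    p <- list(array(0, c(nd, N, T_)), array(0, c(nd, N, T_)))
    dev <- list(array(0, c(nd, N, T_)), array(0, c(nd, N, T_)))
    for (t in seq_len(T_)) {
      shared_t <- D[, b0c, drop = FALSE]
      for (k in seq_len(K)) {
        shared_t <- shared_t + D[, sprintf("bs[%d,%d]", seq_len(N), k),
                                 drop = FALSE] * B[t, k]
      }
      delta_t <- exp(D[, ldc[t]])
      for (j in 1:2) {
        w <- if (j == 1L) delta_t else 1 / delta_t
        gsp <- D[, sprintf("bg[%d,%d]", j, seq_len(N)), drop = FALSE]
        rst <- matrix(0, nd, N)
        for (k in seq_len(K)) {
          rst <- rst + D[, sprintf("rs[%d,%d,%d]", j, seq_len(N), k),
                         drop = FALSE] * B[t, k]
        }
        bt_t <- D[, sprintf("beta[%d,%d]", seq_len(N), t), drop = FALSE]
        trend_t <- drop(D[, sprintf("a[%d,%d]", j, seq_len(K)),
                          drop = FALSE] %*% B[t, ])
        covt <- 0
        if (C) {
          sx <- c("_m", "_f")[j]
          covt <- matrix(0, nd, N)
          for (c in seq_len(C)) {
            covt <- covt + outer(D[, paste0("beta_", fit$cov_names[c], sx)],
                                 X[[c]][, t])
          }
        }
        d_jt <- shared_t * w + gsp + rst + bt_t
        alpha_j <- D[, sprintf("alpha[%d]", j)]
        p[[j]][, , t] <- stats::plogis(alpha_j + trend_t + d_jt + covt)
        dev[[j]][, , t] <- d_jt
      }
    }
    list(p = p, dev = dev)
  }
}

#' Shared-weight and variance-share report for an SCM fit
#'
#' Per wave: the posterior median and 95% interval of the shared weight
#' `delta_t = exp(log delta_t)`, and of the variance shares `eta_j(t)`
#' (proportion of the across-region variance of each sex's predictor
#' explained by the weighted shared component). Shares above 1 (possible
#' under anticorrelation) are counted in the `flagged` attribute.
#'
#' @param fit an SCM `st_fit`.
#' @param basis the fit's basis (defaults to the stored one).
#' @return data.frame with columns `year`, `delta_median`, `delta_lo`,
#'   `delta_hi`, `eta_m_median`, `eta_m_lo`, `eta_m_hi`, `eta_f_*`;
#'   attribute `flagged` counts share draws above 1 per wave.
#' @export
delta_eta_report <- function(fit, basis = fit$basis) {
  stopifnot(inherits(fit, "st_fit"))
  if (fit$model_spec$model != "scm") stop("delta undefined for BYM fits")
  D <- pooled_draws(fit)
  nd <- nrow(D)
  N <- length(fit$region_ids); T_ <- length(fit$waves); K <- basis$K
  B <- fit$basis$B
  b0c <- sprintf("b0[%d]", seq_len(N))
  rows <- list()
  flagged <- integer(T_)
  rowvar <- function(m) {
    mu <- rowMeans(m)
    (rowSums(m * m) - ncol(m) * mu^2) / (ncol(m) - 1)
  }
  for (t in seq_len(T_)) {
    delta_t <- exp(D[, sprintf("log_delta[%d]", t)])
    shared_t <- D[, b0c, drop = FALSE]
    for (k in seq_len(K)) {
      shared_t <- shared_t + D[, sprintf("bs[%d,%d]", seq_len(N), k),
                               drop = FALSE] * B[t, k]
    }
    eta_jt <- list()
    for (j in 1:2) {
      w <- if (j == 1L) delta_t else 1 / delta_t
      sh <- shared_t * w
      gsp <- D[, sprintf("bg[%d,%d]", j, seq_len(N)), drop = FALSE]
      rst <- matrix(0, nd, N)
      for (k in seq_len(K)) {
        rst <- rst + D[, sprintf("rs[%d,%d,%d]", j, seq_len(N), k),
                       drop = FALSE] * B[t, k]
      }
      bt_t <- D[, sprintf("beta[%d,%d]", seq_len(N), t), drop = FALSE]
      num <- rowvar(sh)
      den <- rowvar(sh + gsp + rst + bt_t)
      share <- ifelse(num == 0, 0, num / den)
      flagged[t] <- flagged[t] + sum(share > 1 + 1e-9)
      eta_jt[[j]] <- share
    }
    q <- function(x) stats::quantile(x, c(0.5, 0.025, 0.975), names = FALSE)
    dq <- q(delta_t); mq <- q(eta_jt[[1L]]); fq <- q(eta_jt[[2L]])
    rows[[t]] <- data.frame(
      year = fit$waves[t],
      delta_median = dq[1L], delta_lo = dq[2L], delta_hi = dq[3L],
      eta_m_median = mq[1L], eta_m_lo = mq[2L], eta_m_hi = mq[3L],
      eta_f_median = fq[1L], eta_f_lo = fq[2L], eta_f_hi = fq[3L])
  }
  out <- do.call(rbind, rows)
  attr(out, "flagged") <- flagged
  out
}

#' Covariate effects on the odds-ratio scale
#'
#' Posterior summaries of `exp(coefficient)` per regional covariate (and
#' per sex for the SCM). In time-varying mode the effect at wave `t` is
#' `exp(sum_k gamma_k B_k(t))`, reported per wave.
#'
#' @param fit an `st_fit` fitted with covariates.
#' @param basis the fit's basis.
#' @return data.frame with `covariate`, `sex`, `year` (NA in constant
#'   mode), `or_mean`, `or_median`, `or_lo`, `or_hi`.
#' @export
covariate_report <- function(fit, basis = fit$basis) {
  stopifnot(inherits(fit, "st_fit"))
  if (length(fit$cov_names) == 0L) {
    stop("fit has no covariates; covariate_report undefined")
  }
  D <- pooled_draws(fit)
  scm <- fit$model_spec$model == "scm"
  sex_suffix <- if (scm) c("_m", "_f") else ""
  sex_label <- if (scm) c("m", "f") else "all"
  tv <- fit$model_spec$covariate_mode == "time_varying"
  base_names <- if (tv) {
    unique(sub("\\.B[0-9]+$", "", fit$cov_names))
  } else fit$cov_names
  qs <- function(x) c(mean(x), stats::median(x),
                      stats::quantile(x, c(0.025, 0.975), names = FALSE))
  rows <- list()
  for (s in seq_along(sex_suffix)) {
    for (nm in base_names) {
      if (!tv) {
        or <- exp(D[, paste0("beta_", nm, sex_suffix[s])])
        v <- qs(or)
        rows[[length(rows) + 1L]] <- data.frame(
          covariate = nm, sex = sex_label[s], year = NA_real_,
          or_mean = v[1L], or_median = v[2L], or_lo = v[3L], or_hi = v[4L])
      } else {
        cols <- paste0("beta_", nm, ".B", 0:basis$K, sex_suffix[s])
        G <- D[, cols, drop = FALSE]
        for (t in seq_along(fit$waves)) {
          or <- exp(drop(G %*% c(1, basis$B[t, ])))
          v <- qs(or)
          rows[[length(rows) + 1L]] <- data.frame(
            covariate = nm, sex = sex_label[s], year = fit$waves[t],
            or_mean = v[1L], or_median = v[2L], or_lo = v[3L],
            or_hi = v[4L])
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' DIC model-comparison table
#'
#' Ranks fits of the same data by DIC (ascending), reporting `Dbar` (fit)
#' and `pD` (complexity) alongside.
#'
#' @param fits list of `st_fit` objects on identical data.
#' @param tags optional character labels (default: each fit's model tag).
#' @return data.frame sorted by DIC with columns `model`, `Dbar`, `pD`,
#'   `DIC`, `rank`.
#' @export
compare_models <- function(fits, tags = NULL) {
  if (inherits(fits, "st_fit")) fits <- list(fits)
  if (length(fits) == 0L) stop("no fits supplied")
  fps <- vapply(fits, function(f) f$data_fingerprint, character(1))
  if (length(unique(fps)) != 1L) {
    stop("fits are not on identical data (fingerprints differ)")
  }
  if (is.null(tags)) {
    tags <- vapply(fits, function(f) f$model_tag, character(1))
    if (anyDuplicated(tags)) tags <- make.unique(tags)
  }
  out <- data.frame(
    model = tags,
    Dbar = vapply(fits, function(f) unname(f$dic[["Dbar"]]), numeric(1)),
    pD = vapply(fits, function(f) unname(f$dic[["pD"]]), numeric(1)),
    DIC = vapply(fits, function(f) unname(f$dic[["DIC"]]), numeric(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$DIC), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Serialise a fit to a directory
#'
#' Writes one CSV of draws per chain (full 15-significant-digit formatting),
#' the per-chain deviance traces, and a JSON summary (schema version, model
#' tag, DIC, R-hat, MCMC configuration, data fingerprint).
#'
#' @param fit an `st_fit`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "st_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in seq_along(fit$draws)) {
    utils::write.csv(as.data.frame(fit$draws[[ch]]),
                     file.path(dir, sprintf("draws_chain%d.csv", ch)),
                     row.names = FALSE)
    utils::write.csv(data.frame(deviance = fit$deviance[[ch]]),
                     file.path(dir, sprintf("deviance_chain%d.csv", ch)),
                     row.names = FALSE)
  }
  summary <- list(
    schema_version = "1.0",
    model = fit$model_tag,
    terms = fit$model_spec$terms,
    covariate_mode = fit$model_spec$covariate_mode,
    n_chains = length(fit$draws),
    kept_per_chain = nrow(fit$draws[[1L]]),
    dic = as.list(fit$dic),
    rhat = as.list(round(fit$rhat, 6)),
    mcmc = unclass(fit$mcmc),
    waves = fit$waves,
    region_ids = fit$region_ids,
    sexes = fit$sexes,
    data_fingerprint = fit$data_fingerprint
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
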