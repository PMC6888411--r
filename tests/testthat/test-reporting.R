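# one moderately long shared SCM fit for the reporting contracts
scm_fixture <- local({
  tr <- chns_like_preset("scm")
  sim <- simulate_scm(tr, seed = 41)
  fit <- run_mcmc(model_spec("scm"), sim$panel, sim$basis,
                  mcmc = fast_mcmc(seed = 42))
  list(sim = sim, fit = fit)
})

test_that("risk surfaces summarise every cell and match direct quantiles", {
  fit <- scm_fixture$fit
  surf <- summarize_risk(fit, scm_fixture$sim$panel, force = TRUE)
  expect_equal(nrow(surf), 2 * 7 * 9)
  expect_true(all(surf$p_lo <= surf$p_median & surf$p_median <= surf$p_hi))
  expect_true(all(surf$p_mean > 0 & surf$p_mean < 1))
  expect_true(all(surf$rr_lo <= surf$rr_hi))
  # recompute one cell with an independent quantile routine
  draws <- stprev:::posterior_surfaces(fit, scm_fixture$sim$panel)
  cell <- draws$p[[2]][, 3, 5]
  row <- surf[surf$sex == "f" & surf$region == fit$region_ids[3] &
                surf$year == fit$waves[5], ]
  expect_equal(row$p_mean, mean(cell), tolerance = 1e-12)
  expect_equal(row$p_median, quantile(cell, 0.5, names = FALSE, type = 7),
               tolerance = 1e-12)
  expect_equal(row$p_lo, quantile(cell, 0.025, names = FALSE, type = 7),
               tolerance = 1e-12)
})

test_that("a degenerate posterior collapses mean, median and interval", {
  fit <- scm_fixture$fit
  frozen <- fit
  for (ch in seq_along(frozen$draws)) {
    frozen$draws[[ch]] <- frozen$draws[[1]][rep(1L, 20L), , drop = FALSE]
    frozen$deviance[[ch]] <- rep(frozen$deviance[[1]][1L], 20L)
  }
  surf <- summarize_risk(frozen, scm_fixture$sim$panel, force = TRUE)
  expect_equal(surf$p_mean, surf$p_median, tolerance = 1e-12)
  expect_equal(surf$p_lo, surf$p_hi, tolerance = 1e-12)
  expect_equal(surf$p_mean, surf$p_lo, tolerance = 1e-12)
})

test_that("the convergence gate reports the worst offenders", {
  fit <- scm_fixture$fit
  fit$rhat["alpha[1]"] <- 1.8
  expect_error(summarize_risk(fit, scm_fixture$sim$panel),
               "alpha\\[1\\] 1.8")
  expect_silent({
    x <- summarize_risk(fit, scm_fixture$sim$panel, force = TRUE)
  })
})

test_that("the delta/eta report has one row per wave and honours contracts", {
  rep_ <- delta_eta_report(scm_fixture$fit)
  expect_equal(nrow(rep_), 9L)
  expect_equal(rep_$year, study_waves())
  expect_true(all(rep_$delta_lo <= rep_$delta_median &
                    rep_$delta_median <= rep_$delta_hi))
  expect_true(all(rep_$delta_median > 0))
  expect_true(all(rep_$eta_m_median >= 0 & rep_$eta_f_median >= 0))
  expect_length(attr(rep_, "flagged"), 9L)
  # BYM fits have no shared weight
  pm <- panel_one_sex(scm_fixture$sim$panel, "m")
  fitb <- run_mcmc(model_spec("bym"), pm, scm_fixture$sim$basis,
                   mcmc = fast_mcmc(seed = 43))
  expect_error(delta_eta_report(fitb), "undefined for BYM")
})

test_that("delta medians recover unit truth within their own intervals", {
  rep_ <- delta_eta_report(scm_fixture$fit)
  covered <- rep_$delta_lo <= 1 & 1 <= rep_$delta_hi
  expect_gte(sum(covered), 8L)
})

test_that("covariate reports work in constant and time-varying mode", {
  tr <- chns_like_preset("scm", with_covariates = TRUE)
  sim <- simulate_scm(tr, seed = 44)
  spc <- model_spec("scm", covariate_mode = "constant")
  fit <- run_mcmc(spc, sim$panel, sim$basis,
                  mcmc = fast_mcmc(seed = 45, n_iter = 1000))
  tab <- covariate_report(fit)
  expect_equal(nrow(tab), 2 * 4)
  expect_true(all(is.na(tab$year)))
  expect_true(all(tab$or_lo <= tab$or_median & tab$or_median <= tab$or_hi))

  # zero coefficient draws map to an odds ratio of exactly 1
  fit0 <- fit
  for (ch in seq_along(fit0$draws)) {
    cols <- grep("^beta_", colnames(fit0$draws[[ch]]))
    fit0$draws[[ch]][, cols] <- 0
  }
  tab0 <- covariate_report(fit0)
  expect_equal(tab0$or_mean, rep(1, nrow(tab0)))
  expect_equal(tab0$or_lo, rep(1, nrow(tab0)))

  sptv <- model_spec("scm", covariate_mode = "time_varying")
  fittv <- run_mcmc(sptv, sim$panel, sim$basis,
                    mcmc = fast_mcmc(seed = 46, n_iter = 1000))
  tabtv <- covariate_report(fittv)
  expect_equal(nrow(tabtv), 2 * 4 * 9)  # sex x covariate x wave

  # covariate-free fits are rejected
  expect_error(covariate_report(scm_fixture$fit), "no covariates")
})

test_that("model comparison ranks by DIC and fingerprints the data", {
  sim <- scm_fixture$sim
  pm <- panel_one_sex(sim$panel, "m")
  basis <- sim$basis
  full <- run_mcmc(model_spec("bym"), pm, basis, mcmc = fast_mcmc(seed = 47))
  reduced <- run_mcmc(model_spec("bym", terms = "fixed_spline"), pm, basis,
                      mcmc = fast_mcmc(seed = 47))
  tab <- compare_models(list(full, reduced), tags = c("full", "reduced"))
  expect_equal(tab$DIC, sort(tab$DIC))
  expect_equal(tab$rank, 1:2)
  one <- compare_models(list(full), tags = "only")
  expect_equal(nrow(one), 1L)
  pf <- panel_one_sex(sim$panel, "f")
  other <- run_mcmc(model_spec("bym"), pf, basis, mcmc = fast_mcmc(seed = 48))
  expect_error(compare_models(list(full, other)), "fingerprints differ")
})

test_that("fits serialise to CSV draws plus a JSON summary and read back", {
  dir <- withr::local_tempdir()
  save_fit(scm_fixture$fit, dir)
  expect_true(file.exists(file.path(dir, "draws_chain1.csv")))
  expect_true(file.exists(file.path(dir, "draws_chain2.csv")))
  expect_true(file.exists(file.path(dir, "summary.json")))
  meta <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(meta$model, "scm")
  expect_equal(meta$kept_per_chain, nrow(scm_fixture$fit$draws[[1]]))
  expect_equal(unname(unlist(meta$dic["DIC"])),
               unname(scm_fixture$fit$dic[["DIC"]]), tolerance = 1e-6)
  back <- utils::read.csv(file.path(dir, "draws_chain1.csv"),
                          check.names = FALSE)
  expect_equal(ncol(back), ncol(scm_fixture$fit$draws[[1]]))
  expect_equal(as.numeric(back[["alpha[1]"]]),
               unname(scm_fixture$fit$draws[[1]][, "alpha[1]"]),
               tolerance = 1e-12)
})

test_that("a known positive covariate effect is detected on the odds scale", {
  # contrast-rich regional covariate with a strong true effect; the
  # posterior odds ratio should exceed 1 with its interval excluding 1 in
  # nearly every replicate
  hits <- 0L
  n_rep <- 10L
  for (r in seq_len(n_rep)) {
    tr <- truth_config(
      "bym",
      fixed = list(alpha0 = -1.5, beta_cov = c(overweight = 2)),
      effect_tau = list(u0 = 100, s0 = 100),
      covariate_gen = list(baseline = c(overweight = 0.3),
                           drift = c(overweight = 0.2), region_sd = 0.15))
    sim <- simulate_bym(tr, seed = 700 + r)
    fit <- run_mcmc(model_spec("bym", covariate_mode = "constant"),
                    sim$panel, sim$basis,
                    mcmc = fast_mcmc(seed = 800 + r, n_iter = 3000L))
    tab <- covariate_report(fit)
    expect_gt(tab$or_mean[1], 1)
    if (tab$or_lo[1] > 1) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
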