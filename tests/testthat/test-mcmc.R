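test_that("fits are bit-reproducible for a fixed seed", {
  panel <- random_two_sex_panel(study7_graph(), study_waves(), seed = 1)
  basis <- build_basis(study_waves(), 0)
  cfg <- fast_mcmc(seed = 77)
  f1 <- run_mcmc(model_spec("scm"), panel, basis, mcmc = cfg)
  f2 <- run_mcmc(model_spec("scm"), panel, basis, mcmc = cfg)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$deviance, f2$deviance)
  f3 <- run_mcmc(model_spec("scm"), panel, basis,
                 mcmc = fast_mcmc(seed = 78))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("kept-draw bookkeeping matches chains x ceil((iter - burn)/thin)", {
  panel <- panel_one_sex(
    random_two_sex_panel(study7_graph(), study_waves(), seed = 2), "m")
  basis <- build_basis(study_waves(), 0)
  for (cfg in list(mcmc_config(2, 1001, 500, 3, seed = 1),
                   mcmc_config(3, 900, 450, 7, seed = 1))) {
    fit <- run_mcmc(model_spec("bym"), panel, basis, mcmc = cfg)
    expected <- ceiling((cfg$n_iter - cfg$burn_in) / cfg$thin)
    expect_length(fit$draws, cfg$n_chains)
    for (ch in fit$draws) expect_identical(nrow(ch), as.integer(expected))
    for (dv in fit$deviance) expect_length(dv, expected)
  }
})

test_that("sum-to-zero constraints hold on every kept draw", {
  panel <- random_two_sex_panel(study7_graph(), study_waves(), seed = 3)
  basis <- build_basis(study_waves(), 0)
  fit <- run_mcmc(model_spec("scm"), panel, basis, mcmc = fast_mcmc(seed = 5))
  D <- pooled_draws(fit)
  for (t in c(1, 5, 9)) {
    expect_lt(max(abs(rowSums(
      matrix(D[, sprintf("beta[%d,%d]", 1:7, t)], ncol = 7)))), 1e-9)
  }
  for (k in 1:4) {
    expect_lt(max(abs(rowSums(
      matrix(D[, sprintf("bs[%d,%d]", 1:7, k)], ncol = 7)))), 1e-9)
  }
  pm <- panel_one_sex(panel, "m")
  fitb <- run_mcmc(model_spec("bym"), pm, basis, mcmc = fast_mcmc(seed = 5))
  Db <- pooled_draws(fitb)
  expect_lt(max(abs(rowSums(Db[, sprintf("s[%d]", 1:7)]))), 1e-9)
})

test_that("an intercept-only posterior matches numerical quadrature", {
  g1 <- region_graph("A", NULL)
  panel <- panel_counts(g1, c(2000, 2004), O = matrix(c(30, 30), 1),
                        n = matrix(c(100, 100), 1))
  basis <- build_basis(c(2000, 2004), center_year = 2004)
  fit <- run_mcmc(model_spec("bym", terms = character(0)), panel, basis,
                  mcmc = mcmc_config(seed = 42))
  draws_p <- plogis(pooled_draws(fit)[, "alpha0"])
  f <- function(a) dbinom(60, 200, plogis(a)) * dnorm(a, 0, 100)
  target <- integrate(function(a) plogis(a) * f(a), -20, 20,
                      rel.tol = 1e-10)$value /
    integrate(f, -20, 20, rel.tol = 1e-10)$value
  # Monte-Carlo standard error by batch means over each chain
  batch_means <- unlist(lapply(fit$draws, function(ch) {
    p <- plogis(ch[, "alpha0"])
    tapply(p, rep(seq_len(10), each = length(p) / 10), mean)
  }))
  mcse <- sd(batch_means) / sqrt(length(batch_means))
  expect_lt(abs(mean(draws_p) - target), 3 * mcse)
})

test_that("model/panel mismatches are rejected", {
  panel <- random_two_sex_panel(study7_graph(), study_waves(), seed = 4)
  basis <- build_basis(study_waves(), 0)
  expect_error(run_mcmc(model_spec("bym"), panel, basis), "one sex")
  pm <- panel_one_sex(panel, "m")
  expect_error(run_mcmc(model_spec("scm"), pm, basis), "two-sex")
  basis2 <- build_basis(c(1991, 2015))
  expect_error(run_mcmc(model_spec("bym"), pm, basis2), "waves")
  g_iso <- region_graph(c("A", "B", "C"), rbind(c("A", "B")))
  pan_iso <- panel_counts(g_iso, c(2000, 2004),
                          O = matrix(1, 3, 2), n = matrix(10, 3, 2))
  expect_error(run_mcmc(model_spec("bym"), pan_iso,
                        build_basis(c(2000, 2004))), "isolated")
})

test_that("the C++ deviance trace matches an R recomputation at kept draws", {
  panel <- random_two_sex_panel(study7_graph(), study_waves(), seed = 6)
  basis <- build_basis(study_waves(), 0)
  sp <- model_spec("scm")
  fit <- run_mcmc(sp, panel, basis, mcmc = fast_mcmc(seed = 8))
  D <- fit$draws[[1]]
  for (d in c(1L, 57L, nrow(D))) {
    params <- stprev:::draws_to_params(sp, D[d, ], 7, basis$K, 9,
                                       character(0))
    expect_equal(stprev:::deviance_at(params, sp, panel, basis),
                 fit$deviance[[1]][d], tolerance = 1e-8)
  }
  pm <- panel_one_sex(panel, "m")
  spb <- model_spec("bym")
  fitb <- run_mcmc(spb, pm, basis, mcmc = fast_mcmc(seed = 8))
  Db <- fitb$draws[[2]]
  for (d in c(3L, nrow(Db))) {
    params <- stprev:::draws_to_params(spb, Db[d, ], 7, basis$K, 9,
                                       character(0))
    expect_equal(stprev:::deviance_at(params, spb, pm, basis),
                 fitb$deviance[[2]][d], tolerance = 1e-8)
  }
})

test_that("split-chain BGR behaves on analytic cases", {
  set.seed(10)
  x <- rnorm(2000)
  same <- list(matrix(x[1:1000], dimnames = list(NULL, "p")),
               matrix(x[1001:2000], dimnames = list(NULL, "p")))
  expect_lt(gelman_rubin(same)["p"], 1.01)
  apart <- list(matrix(rnorm(1000, 0, 1), dimnames = list(NULL, "p")),
                matrix(rnorm(1000, 10, 1), dimnames = list(NULL, "p")))
  expect_gt(gelman_rubin(apart)["p"], 2)
  # hand evaluation of the between/within formula on the separated case
  rh <- gelman_rubin(apart)["p"]
  splits <- list(apart[[1]][1:500, ], apart[[1]][501:1000, ],
                 apart[[2]][1:500, ], apart[[2]][501:1000, ])
  W <- mean(vapply(splits, var, 1))
  B <- 500 * var(vapply(splits, mean, 1))
  expect_equal(unname(rh), sqrt((499 / 500 * W + B / 500) / W),
               tolerance = 1e-10)
  # affine invariance
  affine <- lapply(apart, function(m) {
    matrix(3 * m - 7, dimnames = list(NULL, "p"))
  })
  expect_equal(gelman_rubin(affine), gelman_rubin(apart), tolerance = 1e-10)
  expect_error(gelman_rubin(apart[1]), "2 chains")
})

test_that("autocorrelation estimates match known processes", {
  acf0 <- autocorrelation(matrix(rnorm(100), ncol = 1), max_lag = 5)
  expect_equal(unname(acf0[1, 1]), 1)
  set.seed(11)
  iid <- matrix(rnorm(10000), ncol = 1)
  expect_lt(abs(autocorrelation(iid, 1)[2, 1]), 0.05)
  ar1 <- as.numeric(arima.sim(list(ar = 0.9), 10000))
  expect_equal(unname(autocorrelation(matrix(ar1, ncol = 1), 1)[2, 1]),
               0.9, tolerance = 0.05)
  expect_error(autocorrelation(matrix(rnorm(10), ncol = 1), 20),
               "below the chain length")
})

test_that("DIC obeys its identities and degenerate limits", {
  panel <- panel_one_sex(
    random_two_sex_panel(study7_graph(), study_waves(), seed = 12), "m")
  basis <- build_basis(study_waves(), 0)
  fit <- run_mcmc(model_spec("bym"), panel, basis, mcmc = fast_mcmc(seed = 3))
  expect_equal(unname(fit$dic[["DIC"]]),
               unname(fit$dic[["Dbar"]] + fit$dic[["pD"]]))
  # a degenerate posterior (all draws identical) has pD = 0
  frozen <- fit
  for (ch in seq_along(frozen$draws)) {
    frozen$draws[[ch]] <- frozen$draws[[1L]][rep(1L, 50L), , drop = FALSE]
    frozen$deviance[[ch]] <- rep(frozen$deviance[[1L]][1L], 50L)
  }
  dic0 <- compute_dic(frozen, fit$model_spec, panel, basis)
  expect_equal(unname(dic0[["pD"]]), 0, tolerance = 1e-8)
  expect_equal(unname(dic0[["DIC"]]), unname(dic0[["Dbar"]]),
               tolerance = 1e-8)
  expect_error(compute_dic(structure(list(deviance = list()),
                                     class = "st_fit"),
                           fit$model_spec, panel, basis), "empty")
})

test_that("pD approaches one for a single-parameter model", {
  g1 <- region_graph("A", NULL)
  panel <- panel_counts(g1, c(2000, 2004), O = matrix(c(30, 30), 1),
                        n = matrix(c(100, 100), 1))
  basis <- build_basis(c(2000, 2004), center_year = 2004)
  fit <- run_mcmc(model_spec("bym", terms = character(0)), panel, basis,
                  mcmc = mcmc_config(n_iter = 8000, burn_in = 4000,
                                     thin = 2, seed = 19))
  expect_equal(unname(fit$dic[["pD"]]), 1, tolerance = 0.25)
})

test_that("adding an irrelevant parameter block does not decrease pD", {
  panel <- panel_one_sex(
    random_two_sex_panel(study7_graph(), study_waves(), seed = 20), "m")
  basis <- build_basis(study_waves(), 0)
  base <- run_mcmc(model_spec("bym", terms = c("fixed_spline")),
                   panel, basis, mcmc = fast_mcmc(seed = 21, n_iter = 3000))
  extra <- run_mcmc(model_spec("bym",
                               terms = c("fixed_spline", "unstructured")),
                    panel, basis, mcmc = fast_mcmc(seed = 21, n_iter = 3000))
  expect_gte(extra$dic[["pD"]], base$dic[["pD"]] - 0.5)
})
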