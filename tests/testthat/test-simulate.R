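test_that("simulation is seed-deterministic and respects count bounds", {
  tr <- chns_like_preset("scm")
  s1 <- simulate_scm(tr, seed = 5)
  s2 <- simulate_scm(tr, seed = 5)
  expect_identical(s1$panel$O, s2$panel$O)
  expect_identical(s1$params, s2$params)
  expect_true(all(s1$panel$O >= 0 & s1$panel$O <= s1$panel$n))
  expect_true(all(s1$panel$n >= 200 & s1$panel$n <= 1500))
  s3 <- simulate_scm(tr, seed = 6)
  expect_false(identical(s1$panel$O, s3$panel$O))

  trb <- chns_like_preset("bym")
  b1 <- simulate_bym(trb, seed = 5)
  b2 <- simulate_bym(trb, seed = 5)
  expect_identical(b1$panel$O, b2$panel$O)
})

test_that("a flat zero truth simulates prevalence one half", {
  tr <- truth_config("bym", n_range = c(500L, 500L))
  sim <- simulate_bym(tr, seed = 9)
  phat <- sum(sim$panel$O) / sum(sim$panel$n)
  se <- sqrt(0.25 / sum(sim$panel$n))
  expect_lt(abs(phat - 0.5), 3 * se)
  expect_true(all(sim$p == 0.5))
})

test_that("a positive trend raises the final wave above the first", {
  basis <- build_basis(study_waves(), 0)
  curve <- seq(0, 1.5, length.out = 9)
  a_true <- coef(lm.fit(basis$B, curve))
  tr <- truth_config("bym", fixed = list(alpha0 = -1, a = a_true),
                     effect_tau = list(u0 = 50))
  hits <- 0L
  for (s in 1:100) {
    sim <- simulate_bym(tr, seed = s)
    p0 <- sum(sim$panel$O[1, , 1]) / sum(sim$panel$n[1, , 1])
    p1 <- sum(sim$panel$O[1, , 9]) / sum(sim$panel$n[1, , 9])
    if (p1 > p0) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("symmetric truth gives exchangeable sexes", {
  tr <- truth_config("scm", effect_tau = list(b0 = 44, b_shared_spline = 100),
                     fixed = list(alpha = c(-1, -1),
                                  log_delta = numeric(9)))
  nonsig <- 0L
  for (s in 1:100) {
    sim <- simulate_scm(tr, seed = s)
    O <- c(sum(sim$panel$O[1, , ]), sum(sim$panel$O[2, , ]))
    n <- c(sum(sim$panel$n[1, , ]), sum(sim$panel$n[2, , ]))
    pv <- prop.test(O, n)$p.value
    if (pv > 0.01) nonsig <- nonsig + 1L
  }
  expect_gte(nonsig, 95L)
})

test_that("shared-only truth reports unit variance shares", {
  tr <- truth_config("scm", effect_tau = list(b0 = 44, b_shared_spline = 100),
                     fixed = list(log_delta = numeric(9)))
  sim <- simulate_scm(tr, seed = 11)
  expect_equal(unname(sim$eta), matrix(1, 2, 9), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sim$delta, rep(1, 9))
})

test_that("the survey-like preset reproduces its printed anchors", {
  tr <- chns_like_preset("scm")
  expect_equal(tr$waves, c(1991, 1993, 1997, 2000, 2004, 2006, 2009, 2011,
                           2015))
  sim <- simulate_scm(tr, seed = 1)
  pooled91 <- sum(sim$panel$O[, , 1]) / sum(sim$panel$n[, , 1])
  expect_gte(pooled91, 0.08); expect_lte(pooled91, 0.16)
  pooled15 <- sum(sim$panel$O[, , 9]) / sum(sim$panel$n[, , 9])
  expect_gte(pooled15, 0.30); expect_lte(pooled15, 0.38)
  pm <- sum(sim$panel$O[1, , 9]) / sum(sim$panel$n[1, , 9])
  pf <- sum(sim$panel$O[2, , 9]) / sum(sim$panel$n[2, , 9])
  expect_gte(pm, pf)
})

test_that("mean simulated prevalence converges to the fixed-effect surface", {
  # with zero-mean random effects, averaging p over many draws recovers
  # the inverse-logit fixed surface
  basis <- build_basis(study_waves(), 0)
  curve <- seq(-2, -0.5, length.out = 9)
  a_true <- coef(lm.fit(basis$B, curve - curve[1]))
  tr <- truth_config("bym", fixed = list(alpha0 = curve[1], a = a_true),
                     effect_tau = list(u0 = 25, s0 = 25))
  acc <- matrix(0, 7, 9)
  n_rep <- 500L
  for (s in seq_len(n_rep)) acc <- acc + simulate_bym(tr, seed = s)$p
  pbar <- acc / n_rep
  # compare the pooled mean against the logistic-normal mean at 3 MC SEs
  sd_re <- sqrt(1 / 25 + 1 / 25)
  z <- rnorm(20000, 0, sd_re)
  for (t in c(1, 5, 9)) {
    target <- mean(plogis(curve[t] + z))
    se <- sd(plogis(curve[t] + z)) / sqrt(n_rep * 7)
    expect_lt(abs(mean(pbar[, t]) - target), 4 * se + 0.002)
  }
})

test_that("generated covariates drift as configured and stay in range", {
  tr <- chns_like_preset("scm", with_covariates = TRUE)
  sim <- simulate_scm(tr, seed = 3)
  covs <- sim$panel$covariates
  expect_setequal(names(covs),
                  c("age60plus", "overweight", "ever_smoker", "drinker"))
  for (X in covs) expect_true(all(X >= 0.01 & X <= 0.99))
  expect_gt(mean(covs$overweight[, 9]), mean(covs$overweight[, 1]))
})
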