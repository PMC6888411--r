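waves9 <- study_waves()

test_that("zero parameters give prevalence one half everywhere", {
  basis <- build_basis(waves9, 0)
  N <- 7
  pb <- zero_params(model_spec("bym"), random_two_sex_panel(
    study7_graph(), waves9, 1) |> panel_one_sex("m"), basis)
  p <- bym_linear_predictor(pb, basis, prevalence = TRUE)
  expect_equal(dim(p), c(N, 9))
  expect_true(all(p == 0.5))
  panel <- random_two_sex_panel(study7_graph(), waves9, 1)
  ps <- zero_params(model_spec("scm"), panel, basis)
  lp <- scm_linear_predictor(ps, basis, prevalence = TRUE)
  expect_equal(dim(lp), c(2, N, 9))
  expect_true(all(lp == 0.5))
})

test_that("an intercept-only surface reproduces its anchor prevalence", {
  basis <- build_basis(waves9, 0)
  pb <- bym_params(alpha0 = qlogis(0.117), u0 = numeric(7), s0 = numeric(7))
  p <- bym_linear_predictor(pb, basis, prevalence = TRUE)
  expect_equal(unique(as.vector(p)), 0.117, tolerance = 1e-12)
})

test_that("the BYM predictor matches a scalar hand evaluation", {
  basis <- build_basis(waves9, c(-5, 4))
  N <- 7; K <- basis$K
  pb <- random_bym_params(N, K, seed = 5)
  eta <- bym_linear_predictor(pb, basis)
  for (cell in list(c(1, 1), c(4, 5), c(7, 9))) {
    i <- cell[1]; t <- cell[2]
    hand <- pb$alpha0 + sum(pb$a * basis$B[t, ]) + pb$u0[i] + pb$s0[i] +
      sum(pb$b_spline[i, ] * basis$B[t, ])
    expect_equal(eta[i, t], hand, tolerance = 1e-12)
  }
})

test_that("the SCM predictor matches a scalar hand evaluation", {
  basis <- build_basis(waves9, 0)
  N <- 7; K <- basis$K; T_ <- 9
  ps <- random_scm_params(N, K, T_, seed = 6)
  lp <- scm_linear_predictor(ps, basis)
  d <- exp(ps$log_delta)
  for (cell in list(c(1, 2, 3), c(2, 6, 8))) {
    j <- cell[1]; i <- cell[2]; t <- cell[3]
    shared <- ps$b0[i] + sum(ps$b_shared_spline[i, ] * basis$B[t, ])
    w <- if (j == 1) d[t] else 1 / d[t]
    hand <- ps$alpha[j] + shared * w +
      sum(ps$a_gender[j, ] * basis$B[t, ]) + ps$b_gender[j, i] +
      sum(ps$beta_gender_spline[j, i, ] * basis$B[t, ]) + ps$beta_it[i, t]
    expect_equal(lp[j, i, t], hand, tolerance = 1e-12)
  }
})

test_that("a shared-only model with unit weights is sex-symmetric", {
  basis <- build_basis(waves9, 0)
  N <- 7; K <- basis$K
  set.seed(2)
  ps <- scm_params(alpha = c(0, 0), b0 = rnorm(N),
                   b_shared_spline = matrix(rnorm(N * K, 0, 0.2), N, K),
                   log_delta = numeric(9))
  lp <- scm_linear_predictor(ps, basis)
  expect_equal(lp[1, , ], lp[2, , ], tolerance = 1e-12)
})

test_that("constant log weights scale the shared term by exp(2c) between sexes", {
  basis <- build_basis(waves9, 0)
  N <- 7
  cc <- 0.3
  set.seed(3)
  ps <- scm_params(alpha = c(0, 0), b0 = rnorm(N),
                   log_delta = rep(cc, 9))
  lp <- scm_linear_predictor(ps, basis)
  nonzero <- abs(lp[2, , ]) > 1e-12
  expect_true(all(abs(lp[1, , ][nonzero] / lp[2, , ][nonzero] -
                        exp(2 * cc)) < 1e-10))
})

test_that("dimension mismatches name the offending axis", {
  basis <- build_basis(waves9, 0)
  pb <- bym_params(alpha0 = 0, a = c(1, 2), u0 = numeric(7))
  expect_error(bym_linear_predictor(pb, basis), "K = 4")
  pb2 <- bym_params(alpha0 = 0, u0 = numeric(7), s0 = numeric(3))
  expect_error(bym_linear_predictor(pb2, basis), "region axis")
  ps <- scm_params(alpha = c(0, 0), b0 = numeric(7),
                   log_delta = numeric(3))
  expect_error(scm_linear_predictor(ps, basis), "length T")
})

test_that("time-varying covariate design expands one matrix per basis column", {
  tr <- chns_like_preset("scm", with_covariates = TRUE)
  sim <- simulate_scm(tr, seed = 4)
  basis <- sim$basis
  sp_c <- model_spec("scm", covariate_mode = "constant")
  sp_tv <- model_spec("scm", covariate_mode = "time_varying")
  Xc <- covariate_design(sp_c, sim$panel, basis)
  Xtv <- covariate_design(sp_tv, sim$panel, basis)
  expect_equal(length(Xc), 4L)
  expect_equal(length(Xtv), 4L * (basis$K + 1L))
  expect_equal(Xtv[["overweight.B2"]],
               sweep(Xc[["overweight"]], 2L, basis$B[, 2], `*`))
  expect_equal(length(covariate_design(model_spec("scm"), sim$panel, basis)),
               0L)
})
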