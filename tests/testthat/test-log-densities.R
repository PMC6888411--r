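test_that("the ICAR kernel matches hand evaluation on a path graph", {
  g <- region_graph(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  # pairwise squared differences: (x1-x2)^2 + (x2-x3)^2 = 1 + 1 = 2
  expect_equal(log_icar(c(-1, 0, 1), tau = 1, g, include_normalizer = FALSE),
               -1)
  expect_equal(log_icar(c(0, 0, 0), tau = 1, g, include_normalizer = FALSE),
               0)
  expect_equal(log_icar(c(-1, 0, 1), tau = 1, g),
               -1 + (3 - 1) / 2 * log(1))
})

test_that("the ICAR kernel equals the matrix form -tau/2 x'(D-W)x", {
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(3:9, 1)
    g <- random_connected_graph(n)
    x <- rnorm(n); x <- x - mean(x)
    tau <- runif(1, 0.2, 4)
    Q <- laplacian_matrix(g)
    expect_equal(log_icar(x, tau, g, include_normalizer = FALSE),
                 -(tau / 2) * drop(t(x) %*% Q %*% x), tolerance = 1e-10)
  }
})

test_that("ICAR preconditions are enforced", {
  g <- region_graph(c("a", "b", "c"), rbind(c("a", "b")))
  expect_error(log_icar(c(-1, 0, 1), 1, g), "isolated")
  g2 <- region_graph(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  expect_error(log_icar(c(1, 1, 1), 1, g2), "sum to zero")
  expect_error(log_icar(c(-1, 0, 1), -1, g2), "positive")
})

test_that("the MCAR kernel with identity precision is a sum of ICAR kernels", {
  set.seed(21)
  g <- random_connected_graph(6)
  K <- 3
  b <- matrix(rnorm(6 * K), 6, K)
  b <- sweep(b, 2, colMeans(b))
  lhs <- log_mcar(b, diag(K), g, include_normalizer = FALSE)
  rhs <- sum(vapply(seq_len(K), function(k) {
    log_icar(b[, k], 1, g, include_normalizer = FALSE)
  }, numeric(1)))
  expect_equal(lhs, rhs, tolerance = 1e-10)
  expect_equal(log_mcar(b * 0, diag(K), g, include_normalizer = FALSE), 0)
})

test_that("the MCAR kernel equals the dense Kronecker quadratic form", {
  set.seed(22)
  for (rep in 1:10) {
    n <- sample(4:7, 1); K <- sample(2:3, 1)
    g <- random_connected_graph(n)
    b <- matrix(rnorm(n * K), n, K)
    b <- sweep(b, 2, colMeans(b))
    G <- crossprod(matrix(rnorm(K * K), K)) + diag(K)
    Omega <- kronecker(laplacian_matrix(g), G)
    v <- as.vector(t(b))  # vec stacking region-major, K entries per region
    expect_equal(log_mcar(b, G, g, include_normalizer = FALSE),
                 -0.5 * drop(t(v) %*% Omega %*% v), tolerance = 1e-10)
  }
})

test_that("non-SPD MCAR precisions are rejected", {
  g <- random_connected_graph(4)
  b <- matrix(0, 4, 2)
  expect_error(log_mcar(b, matrix(c(1, 2, 2, 1), 2), g), "positive definite")
  expect_error(log_mcar(b, matrix(c(1, 2, 0, 1), 2), g), "symmetric")
})

test_that("the BYM joint matches closed-form binomial terms", {
  g1 <- region_graph("A", NULL)
  panel <- panel_counts(g1, c(2000, 2004),
                        O = matrix(c(3, 3), 1), n = matrix(c(10, 10), 1))
  basis <- build_basis(c(2000, 2004), center_year = 2004)
  spec <- model_spec("bym", terms = character(0))
  params <- bym_params(alpha0 = 0)
  lj <- log_joint_bym(params, panel, basis, spec = spec)
  # two identical cells at p = 0.5, plus the alpha0 prior at zero
  lik <- 2 * (log(choose(10, 3)) + 10 * log(0.5))
  expect_equal(lj, lik + dnorm(0, 0, 100, log = TRUE), tolerance = 1e-10)
})

test_that("zero totals contribute nothing to the likelihood", {
  # the prevalence panel requires totals >= 1, so the n = 0 limit is
  # checked on the likelihood helper itself
  expect_equal(stprev:::binom_loglik(matrix(0, 2, 3), matrix(0, 2, 3),
                                     matrix(rnorm(6), 2, 3)), 0)
})

test_that("the joints are finite for any finite parameters on valid data", {
  panel <- random_two_sex_panel(study7_graph(), study_waves(), seed = 14)
  basis <- build_basis(study_waves(), 0)
  ps <- random_scm_params(7, basis$K, 9, seed = 14)
  expect_true(is.finite(log_joint_scm(ps, panel, basis)))
  pm <- panel_one_sex(panel, "m")
  pb <- random_bym_params(7, basis$K, seed = 14)
  expect_true(is.finite(log_joint_bym(pb, pm, basis)))
})

test_that("the SCM joint decomposes into its named terms", {
  panel <- random_two_sex_panel(study7_graph(), study_waves(), seed = 15)
  basis <- build_basis(study_waves(), 0)
  ps <- random_scm_params(7, basis$K, 9, seed = 15)
  prior <- prior_config()
  lj <- log_joint_scm(ps, panel, basis, prior)
  # independent term-by-term summation
  lp <- scm_linear_predictor(ps, basis)
  terms <- sum(dbinom(panel$O[1, , ], panel$n[1, , ], plogis(lp[1, , ]),
                      log = TRUE)) +
    sum(dbinom(panel$O[2, , ], panel$n[2, , ], plogis(lp[2, , ]),
               log = TRUE)) +
    sum(dnorm(ps$alpha, 0, 100, log = TRUE)) +
    sum(dnorm(ps$a_gender, 0, 100, log = TRUE)) +
    sum(dnorm(ps$b0, 0, 100, log = TRUE)) +
    sum(dnorm(ps$b_gender, 0, 100, log = TRUE)) +
    log_mcar(ps$b_shared_spline, ps$Gamma_b, panel$graph) +
    stprev:::log_wishart_kernel(ps$Gamma_b, diag(basis$K), basis$K) +
    sum(vapply(1:2, function(j) {
      sum(vapply(seq_len(basis$K), function(k) {
        log_icar(ps$beta_gender_spline[j, , k], ps$tau_b, panel$graph)
      }, numeric(1)))
    }, numeric(1))) +
    stprev:::log_tau_prior(ps$tau_b, prior) +
    sum(vapply(1:9, function(t) {
      log_icar(ps$beta_it[, t], ps$tau_beta, panel$graph)
    }, numeric(1))) +
    stprev:::log_tau_prior(ps$tau_beta, prior) +
    sum(dnorm(ps$log_delta, 0, sqrt(0.169), log = TRUE))
  expect_equal(lj, terms, tolerance = 1e-8)
})

test_that("gender relabelling with inverted weights leaves the SCM joint invariant", {
  basis <- build_basis(study_waves(), 0)
  for (seed in 1:5) {
    panel <- random_two_sex_panel(study7_graph(), study_waves(), seed = seed)
    ps <- random_scm_params(7, basis$K, 9, seed = seed)
    lj1 <- log_joint_scm(ps, panel, basis)
    swapped_panel <- panel_counts(
      panel$graph, panel$waves,
      O = panel$O[c(2, 1), , , drop = FALSE],
      n = panel$n[c(2, 1), , , drop = FALSE], sexes = c("m", "f"))
    ps2 <- ps
    ps2$alpha <- ps$alpha[c(2, 1)]
    ps2$a_gender <- ps$a_gender[c(2, 1), , drop = FALSE]
    ps2$b_gender <- ps$b_gender[c(2, 1), , drop = FALSE]
    ps2$beta_gender_spline <- ps$beta_gender_spline[c(2, 1), , ,
                                                    drop = FALSE]
    ps2$log_delta <- -ps$log_delta
    lj2 <- log_joint_scm(ps2, swapped_panel, basis)
    expect_equal(lj1, lj2, tolerance = 1e-10)
  }
})

test_that("the joints are invariant to a consistent region permutation", {
  waves <- study_waves()
  basis <- build_basis(waves, 0)
  g <- study7_graph()
  panel <- random_two_sex_panel(g, waves, seed = 16)
  ps <- random_scm_params(7, basis$K, 9, seed = 16)
  lj1 <- log_joint_scm(ps, panel, basis)
  set.seed(99)
  perm <- sample(7)
  Wp <- g$W[perm, perm]
  gp <- region_graph(g$region_ids[perm],
                     which(upper.tri(Wp) & Wp == 1, arr.ind = TRUE) |>
                       apply(2, function(ix) g$region_ids[perm][ix]))
  panelp <- panel_counts(gp, waves, panel$O[, perm, , drop = FALSE],
                         panel$n[, perm, , drop = FALSE],
                         sexes = c("m", "f"))
  psp <- ps
  psp$b0 <- ps$b0[perm]
  psp$b_shared_spline <- ps$b_shared_spline[perm, , drop = FALSE]
  psp$b_gender <- ps$b_gender[, perm, drop = FALSE]
  psp$beta_gender_spline <- ps$beta_gender_spline[, perm, , drop = FALSE]
  psp$beta_it <- ps$beta_it[perm, , drop = FALSE]
  expect_equal(log_joint_scm(psp, panelp, basis), lj1, tolerance = 1e-10)
})

test_that("weakening the log-delta prior raises the joint at fixed nonzero weights", {
  panel <- random_two_sex_panel(study7_graph(), study_waves(), seed = 17)
  basis <- build_basis(study_waves(), 0)
  ps <- random_scm_params(7, basis$K, 9, seed = 17)
  ps$log_delta <- rep(0.5, 9)
  lj_tight <- log_joint_scm(ps, panel, basis, prior_config())
  lj_loose <- log_joint_scm(ps, panel, basis,
                            prior_config(log_delta_var = 2 * 0.169))
  expect_gt(lj_loose, lj_tight)
})

test_that("the default log-delta prior puts delta^2 in [1/5, 5] with 95% probability", {
  res <- delta_sq_band_probability(0.169, 5, mc_draws = 1e6, seed = 1)
  expect_equal(round(res$exact, 2), 0.95)
  expect_equal(res$mc, res$exact, tolerance = 2e-3)
})

test_that("precision prior variants integrate the right reparameterisations", {
  # variant 2: sigma ~ U(0,1) => P(tau in (a,b)) = sigma(a) - sigma(b)
  pr2 <- prior_config(precision_prior = "unif_sd")
  f2 <- function(tau) exp(stprev:::log_tau_prior(tau, pr2))
  expect_equal(integrate(Vectorize(f2), 1, Inf)$value, 1, tolerance = 1e-6)
  expect_equal(integrate(Vectorize(f2), 4, 25)$value, 1 / 2 - 1 / 5,
               tolerance = 1e-8)
  expect_identical(stprev:::log_tau_prior(0.5, pr2), -Inf)
  # variant 3: sigma^2 ~ halfN(0, 100)
  pr3 <- prior_config(precision_prior = "halfnormal_var")
  f3 <- function(tau) exp(stprev:::log_tau_prior(tau, pr3))
  expect_equal(integrate(Vectorize(f3), 1e-6, Inf)$value, 1,
               tolerance = 1e-4)
})
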