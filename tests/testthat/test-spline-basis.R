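test_that("year centring is elementwise subtraction of the reference", {
  expect_equal(center_years(2004, 2004), 0)
  expect_equal(center_years(c(1991, 2015), 2004), c(-13, 11))
  expect_error(center_years(numeric(0)), "nonempty")
})

test_that("the basis has K = L + 3 columns for L = 0..3", {
  waves <- study_waves()
  for (L in 0:3) {
    knots <- if (L == 0) numeric(0) else seq(-6, 6, length.out = L)
    sb <- build_basis(waves, interior_knots = knots)
    expect_identical(sb$K, L + 3L)
    expect_identical(ncol(sb$B), L + 3L)
  }
})

test_that("the full clamped basis rows sum to one and entries lie in [0,1]", {
  waves <- study_waves()
  for (knots in list(numeric(0), 0, c(-5, 0, 4))) {
    sb <- build_basis(waves, interior_knots = knots)
    full <- stprev:::full_clamped_basis(sb$t_values, sb$interior_knots,
                                        min(sb$t_values), max(sb$t_values))
    expect_equal(ncol(full), length(knots) + 4L)
    expect_equal(rowSums(full), rep(1, length(waves)), tolerance = 1e-12)
    expect_true(all(full >= 0 & full <= 1 + 1e-12))
    expect_true(all(sb$B >= 0 & sb$B <= 1 + 1e-12))
  }
})

test_that("basis evaluation matches an independent Cox-de Boor recurrence", {
  set.seed(31)
  for (rep in 1:10) {
    lo <- -13; hi <- 11
    L <- sample(0:4, 1)
    knots <- sort(runif(L, lo + 1, hi - 1))
    x <- sort(c(lo, runif(6, lo, hi), hi))
    ours <- stprev:::full_clamped_basis(x, knots, lo, hi)
    ref <- cox_de_boor_basis(x, knots, lo, hi)
    expect_equal(ours, ref, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("each basis column is nonnegative with full column rank", {
  sb <- build_basis(study_waves(), interior_knots = c(-5, 0, 4))
  expect_true(all(sb$B >= 0))
  expect_identical(qr(sb$B)$rank, sb$K)
})

test_that("invalid knot configurations are rejected", {
  waves <- study_waves()
  expect_error(build_basis(waves, interior_knots = c(0, 0)), "duplicate")
  expect_error(build_basis(waves, interior_knots = -13), "strictly inside")
  expect_error(build_basis(waves, interior_knots = 99), "strictly inside")
})

test_that("eval_basis agrees with the construction grid and guards range", {
  sb <- build_basis(study_waves(), interior_knots = 0)
  expect_equal(eval_basis(sb, sb$t_values), unname(sb$B),
               ignore_attr = TRUE)
  expect_error(eval_basis(sb, 12), "outside")
})

test_that("forward selection honours its trivial contracts", {
  panel <- random_two_sex_panel(study7_graph(), study_waves(), seed = 9)
  pm <- panel_one_sex(panel, "m")
  sp <- model_spec("bym")
  # stub DIC evaluator: fewer knots always better
  stub <- function(data, spec, knots) list(dic = 100 + 5 * length(knots))
  res <- forward_knot_selection(pm, sp, candidate_knots = numeric(0),
                                fit_fn = stub)
  expect_equal(res$knots, 0)
  expect_equal(nrow(res$trace), 1L)
  res2 <- forward_knot_selection(pm, sp, candidate_knots = c(-5, 4),
                                 fit_fn = stub, dic_drop_threshold = Inf)
  expect_equal(res2$knots, 0)
  # improving evaluator: adds the best knot then stops
  better <- function(data, spec, knots) {
    list(dic = 100 - 10 * (-5 %in% knots) - 1 * (4 %in% knots))
  }
  res3 <- forward_knot_selection(pm, sp, candidate_knots = c(-5, 4),
                                 fit_fn = better, dic_drop_threshold = 2)
  expect_equal(res3$knots, c(-5, 0))
  expect_equal(res3$dic, 90)
  # fit failures propagate with the offending knot set named
  boom <- function(data, spec, knots) stop("bad fit")
  expect_error(forward_knot_selection(pm, sp, candidate_knots = 1,
                                      fit_fn = boom),
               "knot set \\{0\\}")
})

test_that("forward selection stays at the true knot under a real fit", {
  # data generated with a single interior knot at 0 and visible curvature;
  # selection starting from {0} should not add spurious knots in most
  # replicates
  waves <- study_waves()
  basis0 <- build_basis(waves, 0)
  curve <- -1.5 + 0.08 * basis0$t_values - 0.006 * basis0$t_values^2
  a_true <- coef(lm.fit(basis0$B, curve - curve[1]))
  tr <- truth_config("bym",
                     fixed = list(alpha0 = curve[1], a = a_true),
                     effect_tau = list(u0 = 100, s0 = 100),
                     n_range = c(400L, 900L))
  hits <- 0L
  n_rep <- 5L
  for (r in seq_len(n_rep)) {
    sim <- simulate_bym(tr, seed = 300 + r)
    res <- forward_knot_selection(
      sim$panel, model_spec("bym"), candidate_knots = c(-9, 5),
      fit_fn = fit_dic_fn(mcmc = fast_mcmc(seed = r)),
      dic_drop_threshold = 2)
    if (identical(res$knots, 0)) hits <- hits + 1L
    expect_true(0 %in% res$knots)
  }
  expect_gte(hits, ceiling(0.8 * n_rep))
})
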