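// Adaptive Metropolis-within-Gibbs samplers for the binomial-logit
// spatio-temporal BYM and shared component models.
//
// Scalar precisions with gamma priors and the Wishart-prior MCAR precision
// are updated by conjugate Gibbs steps; everything else uses random-walk
// Metropolis with per-block proposal scales adapted during burn-in only
// (frozen afterwards, so the kept draws come from a fixed-kernel chain).
// Intrinsic CAR blocks are recentred after each sweep (GeoBUGS car.normal
// convention); where an exactly-confounded fixed effect exists, the
// subtracted mean is transferred to it so the linear predictor is
// unchanged.
//
// All randomness goes through R's RNG, so results are reproducible from
// set.seed() on the R side.

#include <RcppArmadillo.h>
#include <functional>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Binomial log-likelihood kernel: O * eta - n * log(1 + exp(eta)).
// The binomial coefficient is constant in the parameters and cancels from
// every Metropolis ratio; full deviances are computed separately.
static inline double ll_kernel(double O, double n, double eta) {
  double lse = (eta > 30.0) ? eta : std::log1p(std::exp(eta));
  return O * eta - n * lse;
}

static inline double inv_logit(double x) {
  return 1.0 / (1.0 + std::exp(-x));
}

// log N(x; 0, sd) density
static inline double ldnorm0(double x, double sd) {
  return -0.918938533204672742 - std::log(sd) - x * x / (2.0 * sd * sd);
}

// Full -2 log-likelihood (with binomial coefficients) of one N x T slab.
static double deviance_slab(const arma::mat& O, const arma::mat& n,
                            const arma::mat& lp) {
  double ll = 0.0;
  for (arma::uword i = 0; i < O.n_rows; ++i)
    for (arma::uword t = 0; t < O.n_cols; ++t)
      ll += R::dbinom(O(i, t), n(i, t), inv_logit(lp(i, t)), 1);
  return -2.0 * ll;
}

// ---- adaptive proposal scales -------------------------------------------

struct AdaptScale {
  double ls;       // log proposal sd
  int acc, tot;
  double target;
  AdaptScale(double s = 0.2, double targ = 0.44)
    : ls(std::log(s)), acc(0), tot(0), target(targ) {}
  double sd() const { return std::exp(ls); }
  void hit(bool accepted) { tot++; if (accepted) acc++; }
  void adapt(int batch) {
    if (tot == 0) return;
    double rate = double(acc) / double(tot);
    double step = std::min(0.25, 1.0 / std::sqrt(double(batch)));
    ls += (rate > target) ? step : -step;
    ls = std::min(std::max(ls, -8.0), 4.0);
    acc = 0; tot = 0;
  }
};

// ---- precision updates ---------------------------------------------------

// Log prior density of tau under the sensitivity variant
// (1 = gamma on tau, 2 = sigma ~ U(0,1), 3 = sigma^2 ~ halfN(0, 100)).
static double log_tau_prior_cpp(double tau, int variant, double shape,
                                double rate) {
  if (tau <= 0.0) return R_NegInf;
  switch (variant) {
  case 1: return R::dgamma(tau, shape, 1.0 / rate, 1);
  case 2:
    if (tau < 1.0) return R_NegInf;
    return std::log(0.5) - 1.5 * std::log(tau);
  default: {
    double v = 1.0 / tau;
    return std::log(2.0) - 0.5 * std::log(2.0 * M_PI * 100.0)
      - v * v / 200.0 - 2.0 * std::log(tau);
  }
  }
}

// Update a precision whose conditional is proportional to
// tau^halfdf * exp(-tau * halfquad) * prior(tau).
static double update_tau(double tau, double halfdf, double halfquad,
                         int variant, double shape, double rate,
                         AdaptScale& sc, bool adapt_now) {
  if (variant == 1) {
    return R::rgamma(shape + halfdf, 1.0 / (rate + halfquad));
  }
  double lt = std::log(tau);
  double ltp = lt + R::rnorm(0.0, sc.sd());
  double taup = std::exp(ltp);
  double dl = halfdf * (ltp - lt) - (taup - tau) * halfquad
    + log_tau_prior_cpp(taup, variant, shape, rate)
    - log_tau_prior_cpp(tau, variant, shape, rate)
    + (ltp - lt);  // Jacobian of the log-scale walk
  bool ok = std::log(R::runif(0.0, 1.0)) < dl;
  if (adapt_now) sc.hit(ok);
  return ok ? taup : tau;
}

// Wishart draw in the BUGS parameterisation: density prop. to
// |G|^((df-K-1)/2) exp(-tr(Rate G)/2); sampled via Bartlett decomposition
// with scale matrix inv(Rate), using R's RNG.
static arma::mat rwishart_rate(double df, const arma::mat& Rate) {
  arma::uword K = Rate.n_rows;
  arma::mat S = arma::inv_sympd(arma::symmatu(Rate));
  arma::mat L = arma::chol(S, "lower");
  arma::mat A(K, K, arma::fill::zeros);
  for (arma::uword i = 0; i < K; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - double(i)));
    for (arma::uword j = 0; j < i; ++j) A(i, j) = R::rnorm(0.0, 1.0);
  }
  arma::mat LA = L * A;
  return LA * LA.t();
}

// ---- shared small helpers ------------------------------------------------

struct Graph {
  int N;
  std::vector<std::vector<int>> nb;
  arma::umat edges;  // E x 2, 0-based
  explicit Graph(const IntegerMatrix& e, int N_) : N(N_), nb(N_) {
    edges.set_size(e.nrow(), 2);
    for (int r = 0; r < e.nrow(); ++r) {
      int a = e(r, 0), b = e(r, 1);
      edges(r, 0) = a; edges(r, 1) = b;
      nb[a].push_back(b);
      nb[b].push_back(a);
    }
  }
};

// Sum over edges of (x_i - x_j)^2.
static double icar_quad(const arma::vec& x, const Graph& g) {
  double q = 0.0;
  for (arma::uword r = 0; r < g.edges.n_rows; ++r) {
    double d = x(g.edges(r, 0)) - x(g.edges(r, 1));
    q += d * d;
  }
  return q;
}

// K x K cross-product sum over edges of (b_i - b_j)(b_i - b_j)^T.
static arma::mat mcar_crossprod(const arma::mat& b, const Graph& g) {
  arma::mat S(b.n_cols, b.n_cols, arma::fill::zeros);
  for (arma::uword r = 0; r < g.edges.n_rows; ++r) {
    arma::rowvec d = b.row(g.edges(r, 0)) - b.row(g.edges(r, 1));
    S += d.t() * d;
  }
  return S;
}

static std::vector<arma::mat> design_list(const List& Xd) {
  std::vector<arma::mat> X;
  for (int c = 0; c < Xd.size(); ++c) {
    X.push_back(as<arma::mat>(Xd[c]));
  }
  return X;
}

// =========================================================================
// BYM sampler
// =========================================================================

// [[Rcpp::export]]
List bym_sampler_cpp(const arma::mat& O, const arma::mat& n,
                     const arma::mat& B, IntegerMatrix edges,
                     List Xd, List init, List prior_list, List term_list,
                     int n_iter, int burn_in, int thin) {
  const int N = O.n_rows, T = O.n_cols, K = B.n_cols;
  Graph g(edges, N);
  std::vector<arma::mat> X = design_list(Xd);
  const int C = X.size();

  const bool t_fix = as<bool>(term_list["fixed_spline"]);
  const bool t_u   = as<bool>(term_list["unstructured"]);
  const bool t_s   = as<bool>(term_list["spatial"]);
  const bool t_rs  = as<bool>(term_list["random_spline"]);

  const double sdf = std::sqrt(as<double>(prior_list["fixed_effect_var"]));
  const double shp = as<double>(prior_list["tau_shape"]);
  const double rte = as<double>(prior_list["tau_rate"]);
  const int variant = as<int>(prior_list["precision_variant"]);
  const double wdf = as<double>(prior_list["wishart_df"]);
  const arma::mat wR = as<arma::mat>(prior_list["wishart_R"]);

  // state
  double alpha0 = as<double>(init["alpha0"]);
  arma::vec a = as<arma::vec>(init["a"]);
  arma::vec u = as<arma::vec>(init["u0"]);
  arma::vec s = as<arma::vec>(init["s0"]);
  arma::mat b = as<arma::mat>(init["b_spline"]);
  arma::vec gc = as<arma::vec>(init["beta_cov"]);
  double tau_u = as<double>(init["tau_u"]);
  double tau_s = as<double>(init["tau_s"]);
  arma::mat Gam = as<arma::mat>(init["Gamma"]);

  // linear predictor and cached likelihood kernel
  arma::mat lp(N, T);
  arma::mat llc(N, T);
  auto rebuild_lp = [&]() {
    arma::mat trend = B * a;  // T x 1
    for (int i = 0; i < N; ++i)
      for (int t = 0; t < T; ++t) {
        double e = alpha0 + trend(t) + u(i) + s(i)
          + arma::dot(b.row(i), B.row(t));
        for (int c = 0; c < C; ++c) e += gc(c) * X[c](i, t);
        lp(i, t) = e;
        llc(i, t) = ll_kernel(O(i, t), n(i, t), e);
      }
  };
  rebuild_lp();

  // proposal scales
  AdaptScale sc_alpha(0.1), sc_u(0.2), sc_s(0.2), sc_sw(0.3);
  std::vector<AdaptScale> sc_a(K, AdaptScale(0.1));
  std::vector<AdaptScale> sc_c(C, AdaptScale(0.1));
  AdaptScale sc_b(0.2, 0.23);
  AdaptScale sc_tu(0.5), sc_ts(0.5), sc_itu(0.5), sc_its(0.5);

  // global shift of lp by d (alpha0-like or column-profile moves)
  auto try_global = [&](double d, double dprior) -> bool {
    double dl = dprior;
    arma::mat lln(N, T);
    for (int i = 0; i < N; ++i)
      for (int t = 0; t < T; ++t) {
        lln(i, t) = ll_kernel(O(i, t), n(i, t), lp(i, t) + d);
        dl += lln(i, t) - llc(i, t);
      }
    if (std::log(R::runif(0.0, 1.0)) < dl) {
      lp += d; llc = lln;
      return true;
    }
    return false;
  };

  const int n_keep = (n_iter - burn_in + thin - 1) / thin;
  const int P = 1 + K + N + N + N * K + C + 2 + K * K;
  arma::mat draws(n_keep, P);
  arma::vec dev(n_keep);
  int kept = 0, batch = 0;

  for (int iter = 0; iter < n_iter; ++iter) {
    bool adapting = iter < burn_in;

    { // alpha0
      double d = R::rnorm(0.0, sc_alpha.sd());
      double dp = ldnorm0(alpha0 + d, sdf)
        - ldnorm0(alpha0, sdf);
      bool ok = try_global(d, dp);
      if (ok) alpha0 += d;
      if (adapting) sc_alpha.hit(ok);
    }

    if (t_fix) { // fixed spline coefficients
      for (int k = 0; k < K; ++k) {
        double d = R::rnorm(0.0, sc_a[k].sd());
        double dl = ldnorm0(a(k) + d, sdf)
          - ldnorm0(a(k), sdf);
        arma::mat lln(N, T);
        for (int t = 0; t < T; ++t) {
          double dd = d * B(t, k);
          for (int i = 0; i < N; ++i) {
            lln(i, t) = ll_kernel(O(i, t), n(i, t), lp(i, t) + dd);
            dl += lln(i, t) - llc(i, t);
          }
        }
        bool ok = std::log(R::runif(0.0, 1.0)) < dl;
        if (ok) {
          a(k) += d;
          for (int t = 0; t < T; ++t) lp.col(t) += d * B(t, k);
          llc = lln;
        }
        if (adapting) sc_a[k].hit(ok);
      }
    }

    for (int c = 0; c < C; ++c) { // covariate coefficients
      double d = R::rnorm(0.0, sc_c[c].sd());
      double dl = ldnorm0(gc(c) + d, sdf)
        - ldnorm0(gc(c), sdf);
      arma::mat lln(N, T);
      for (int i = 0; i < N; ++i)
        for (int t = 0; t < T; ++t) {
          lln(i, t) = ll_kernel(O(i, t), n(i, t), lp(i, t) + d * X[c](i, t));
          dl += lln(i, t) - llc(i, t);
        }
      bool ok = std::log(R::runif(0.0, 1.0)) < dl;
      if (ok) { gc(c) += d; lp += d * X[c]; llc = lln; }
      if (adapting) sc_c[c].hit(ok);
    }

    if (t_u) { // unstructured effects
      for (int i = 0; i < N; ++i) {
        double d = R::rnorm(0.0, sc_u.sd());
        double up = u(i) + d;
        double dl = -0.5 * tau_u * (up * up - u(i) * u(i));
        arma::rowvec lln(T);
        for (int t = 0; t < T; ++t) {
          lln(t) = ll_kernel(O(i, t), n(i, t), lp(i, t) + d);
          dl += lln(t) - llc(i, t);
        }
        bool ok = std::log(R::runif(0.0, 1.0)) < dl;
        if (ok) { u(i) = up; lp.row(i) += d; llc.row(i) = lln; }
        if (adapting) sc_u.hit(ok);
      }
      // transfer the level to alpha0 (lp unchanged); u and alpha0 are
      // exactly confounded otherwise
      double mu = arma::mean(u);
      u -= mu;
      alpha0 += mu;
    }

    if (t_s) { // ICAR spatial effects
      for (int i = 0; i < N; ++i) {
        double d = R::rnorm(0.0, sc_s.sd());
        double sp = s(i) + d;
        double dq = 0.0;
        for (int j : g.nb[i]) {
          double d1 = sp - s(j), d0 = s(i) - s(j);
          dq += d1 * d1 - d0 * d0;
        }
        double dl = -0.5 * tau_s * dq;
        arma::rowvec lln(T);
        for (int t = 0; t < T; ++t) {
          lln(t) = ll_kernel(O(i, t), n(i, t), lp(i, t) + d);
          dl += lln(t) - llc(i, t);
        }
        bool ok = std::log(R::runif(0.0, 1.0)) < dl;
        if (ok) { s(i) = sp; lp.row(i) += d; llc.row(i) = lln; }
        if (adapting) sc_s.hit(ok);
      }
      // swap move along the confounded u_i/s_i direction (likelihood
      // invariant; only the two priors change)
      if (t_u) {
        for (int i = 0; i < N; ++i) {
          double m = R::rnorm(0.0, sc_sw.sd());
          double dq = 0.0;
          for (int j : g.nb[i]) {
            double d1 = (s(i) - m) - s(j), d0 = s(i) - s(j);
            dq += d1 * d1 - d0 * d0;
          }
          double dl = -0.5 * tau_u * ((u(i) + m) * (u(i) + m) - u(i) * u(i))
            - 0.5 * tau_s * dq;
          bool ok = std::log(R::runif(0.0, 1.0)) < dl;
          if (ok) { u(i) += m; s(i) -= m; }
          if (adapting) sc_sw.hit(ok);
        }
      }
      // recentre; transfer the level to alpha0 (lp unchanged)
      double m = arma::mean(s);
      s -= m;
      alpha0 += m;
    }

    if (t_rs) { // MCAR random spline rows
      for (int i = 0; i < N; ++i) {
        arma::rowvec d(K);
        for (int k = 0; k < K; ++k) d(k) = R::rnorm(0.0, sc_b.sd());
        arma::rowvec bi = b.row(i), bp = bi + d;
        double dq = 0.0;
        for (int j : g.nb[i]) {
          arma::rowvec d1 = bp - b.row(j), d0 = bi - b.row(j);
          dq += arma::as_scalar(d1 * Gam * d1.t() - d0 * Gam * d0.t());
        }
        double dl = -0.5 * dq;
        arma::rowvec lln(T);
        for (int t = 0; t < T; ++t) {
          double dd = arma::dot(d, B.row(t));
          lln(t) = ll_kernel(O(i, t), n(i, t), lp(i, t) + dd);
          dl += lln(t) - llc(i, t);
        }
        bool ok = std::log(R::runif(0.0, 1.0)) < dl;
        if (ok) {
          b.row(i) = bp;
          for (int t = 0; t < T; ++t) lp(i, t) += arma::dot(d, B.row(t));
          llc.row(i) = lln;
        }
        if (adapting) sc_b.hit(ok);
      }
      // recentre each column; transfer to the fixed spline when present
      arma::rowvec m = arma::mean(b, 0);
      b.each_row() -= m;
      if (t_fix) {
        a += m.t();
      } else {
        for (int t = 0; t < T; ++t) {
          double shift = arma::dot(m, B.row(t));
          lp.col(t) -= shift;
        }
        for (int i = 0; i < N; ++i)
          for (int t = 0; t < T; ++t)
            llc(i, t) = ll_kernel(O(i, t), n(i, t), lp(i, t));
      }
    }

    // precisions
    if (t_u) {
      tau_u = update_tau(tau_u, N / 2.0, 0.5 * arma::dot(u, u),
                         variant, shp, rte, sc_tu, adapting);
    }
    if (t_s) {
      tau_s = update_tau(tau_s, (N - 1) / 2.0, 0.5 * icar_quad(s, g),
                         variant, shp, rte, sc_ts, adapting);
    }
    // interweaved (ancillary) precision moves: rescale the whole block
    // while holding its standardised form fixed, so block scale and
    // precision move together and the funnel between them mixes
    if (t_u) {
      double lt = std::log(tau_u);
      double ltp = lt + R::rnorm(0.0, sc_itu.sd());
      double c = std::exp(0.5 * (lt - ltp));  // u' = u * c
      double dl = log_tau_prior_cpp(std::exp(ltp), variant, shp, rte)
        - log_tau_prior_cpp(tau_u, variant, shp, rte) + (ltp - lt);
      arma::mat lln(N, T);
      for (int i = 0; i < N; ++i) {
        double d = (c - 1.0) * u(i);
        for (int t = 0; t < T; ++t) {
          lln(i, t) = ll_kernel(O(i, t), n(i, t), lp(i, t) + d);
          dl += lln(i, t) - llc(i, t);
        }
      }
      bool ok = std::log(R::runif(0.0, 1.0)) < dl;
      if (ok) {
        for (int i = 0; i < N; ++i) lp.row(i) += (c - 1.0) * u(i);
        u *= c; tau_u = std::exp(ltp); llc = lln;
      }
      if (adapting) sc_itu.hit(ok);
    }
    if (t_s) {
      double lt = std::log(tau_s);
      double ltp = lt + R::rnorm(0.0, sc_its.sd());
      double c = std::exp(0.5 * (lt - ltp));
      double dl = log_tau_prior_cpp(std::exp(ltp), variant, shp, rte)
        - log_tau_prior_cpp(tau_s, variant, shp, rte) + (ltp - lt);
      arma::mat lln(N, T);
      for (int i = 0; i < N; ++i) {
        double d = (c - 1.0) * s(i);
        for (int t = 0; t < T; ++t) {
          lln(i, t) = ll_kernel(O(i, t), n(i, t), lp(i, t) + d);
          dl += lln(i, t) - llc(i, t);
        }
      }
      bool ok = std::log(R::runif(0.0, 1.0)) < dl;
      if (ok) {
        for (int i = 0; i < N; ++i) lp.row(i) += (c - 1.0) * s(i);
        s *= c; tau_s = std::exp(ltp); llc = lln;
      }
      if (adapting) sc_its.hit(ok);
    }
    if (t_rs) {
      arma::mat Sb = mcar_crossprod(b, g);
      Gam = rwishart_rate(wdf + double(N - 1), wR + Sb);
    }

    if (adapting && (iter + 1) % 50 == 0) {
      batch++;
      sc_alpha.adapt(batch); sc_u.adapt(batch); sc_s.adapt(batch);
      sc_sw.adapt(batch);
      sc_b.adapt(batch); sc_tu.adapt(batch); sc_ts.adapt(batch);
      sc_itu.adapt(batch); sc_its.adapt(batch);
      for (auto& sck : sc_a) sck.adapt(batch);
      for (auto& scc : sc_c) scc.adapt(batch);
    }

    if (iter >= burn_in && (iter - burn_in) % thin == 0) {
      int p = 0;
      draws(kept, p++) = alpha0;
      for (int k = 0; k < K; ++k) draws(kept, p++) = a(k);
      for (int i = 0; i < N; ++i) draws(kept, p++) = u(i);
      for (int i = 0; i < N; ++i) draws(kept, p++) = s(i);
      for (int k = 0; k < K; ++k)
        for (int i = 0; i < N; ++i) draws(kept, p++) = b(i, k);
      for (int c = 0; c < C; ++c) draws(kept, p++) = gc(c);
      draws(kept, p++) = tau_u;
      draws(kept, p++) = tau_s;
      for (int l = 0; l < K; ++l)
        for (int k = 0; k < K; ++k) draws(kept, p++) = Gam(k, l);
      dev(kept) = deviance_slab(O, n, lp);
      kept++;
    }
  }

  return List::create(_["draws"] = draws, _["deviance"] = dev);
}

// =========================================================================
// SCM sampler
// =========================================================================

// [[Rcpp::export]]
List scm_sampler_cpp(const arma::mat& O1, const arma::mat& n1,
                     const arma::mat& O2, const arma::mat& n2,
                     const arma::mat& B, IntegerMatrix edges,
                     List Xd, List init, List prior_list, List term_list,
                     int n_iter, int burn_in, int thin) {
  const int N = O1.n_rows, T = O1.n_cols, K = B.n_cols;
  Graph g(edges, N);
  std::vector<arma::mat> X = design_list(Xd);
  const int C = X.size();

  const bool t_b0  = as<bool>(term_list["shared_spatial"]);
  const bool t_bs  = as<bool>(term_list["shared_spline"]);
  const bool t_ag  = as<bool>(term_list["gender_spline_fixed"]);
  const bool t_bg  = as<bool>(term_list["gender_spatial"]);
  const bool t_rs  = as<bool>(term_list["gender_spline_random"]);
  const bool t_int = as<bool>(term_list["interaction"]);
  const bool t_dw  = as<bool>(term_list["delta_weights"]);

  const double sdf = std::sqrt(as<double>(prior_list["fixed_effect_var"]));
  const double shp = as<double>(prior_list["tau_shape"]);
  const double rte = as<double>(prior_list["tau_rate"]);
  const double ld_sd = std::sqrt(as<double>(prior_list["log_delta_var"]));
  const int variant = as<int>(prior_list["precision_variant"]);
  const double wdf = as<double>(prior_list["wishart_df"]);
  const arma::mat wR = as<arma::mat>(prior_list["wishart_R"]);

  arma::vec alpha = as<arma::vec>(init["alpha"]);           // 2
  arma::mat ag = as<arma::mat>(init["a_gender"]);           // 2 x K
  arma::vec b0 = as<arma::vec>(init["b0"]);                 // N
  arma::mat bs = as<arma::mat>(init["b_shared_spline"]);    // N x K
  arma::mat bg = as<arma::mat>(init["b_gender"]);           // 2 x N
  arma::cube rs = as<arma::cube>(init["beta_gender_spline"]); // N x K x 2
  arma::mat bt = as<arma::mat>(init["beta_it"]);            // N x T
  arma::vec ld = as<arma::vec>(init["log_delta"]);          // T
  arma::mat gc = as<arma::mat>(init["beta_cov"]);           // 2 x C
  double tau_beta = as<double>(init["tau_beta"]);
  double tau_b = as<double>(init["tau_b"]);
  arma::mat Gam = as<arma::mat>(init["Gamma_b"]);

  arma::vec delta = arma::exp(ld);
  arma::mat shared(N, T);       // b0_i + sum_k bs_ik B_k(t)
  arma::mat lp1(N, T), lp2(N, T), ll1(N, T), ll2(N, T);

  auto rebuild = [&]() {
    for (int i = 0; i < N; ++i)
      for (int t = 0; t < T; ++t) {
        shared(i, t) = b0(i) + arma::dot(bs.row(i), B.row(t));
        double g1 = alpha(0) + shared(i, t) * delta(t)
          + arma::dot(ag.row(0), B.row(t)) + bg(0, i)
          + arma::dot(rs.slice(0).row(i), B.row(t)) + bt(i, t);
        double g2 = alpha(1) + shared(i, t) / delta(t)
          + arma::dot(ag.row(1), B.row(t)) + bg(1, i)
          + arma::dot(rs.slice(1).row(i), B.row(t)) + bt(i, t);
        for (int c = 0; c < C; ++c) {
          g1 += gc(0, c) * X[c](i, t);
          g2 += gc(1, c) * X[c](i, t);
        }
        lp1(i, t) = g1; lp2(i, t) = g2;
        ll1(i, t) = ll_kernel(O1(i, t), n1(i, t), g1);
        ll2(i, t) = ll_kernel(O2(i, t), n2(i, t), g2);
      }
  };
  rebuild();

  AdaptScale sc_al1(0.1), sc_al2(0.1), sc_b0(0.2), sc_bg(0.2), sc_sw(0.3);
  std::vector<AdaptScale> sc_ag(2 * K, AdaptScale(0.1));
  std::vector<AdaptScale> sc_gc(2 * C, AdaptScale(0.1));
  AdaptScale sc_bs(0.15, 0.23), sc_rs(0.15, 0.23), sc_bt(0.25), sc_ld(0.2);
  AdaptScale sc_tb(0.5), sc_tbb(0.5);

  // Metropolis step shifting sex j's predictor by a per-cell amount given
  // by shift(i, t); returns acceptance.
  auto try_shift = [&](int j, double dprior,
                       const std::function<double(int, int)>& shift) -> bool {
    const arma::mat& Oj = (j == 0) ? O1 : O2;
    const arma::mat& nj = (j == 0) ? n1 : n2;
    arma::mat& lpj = (j == 0) ? lp1 : lp2;
    arma::mat& llj = (j == 0) ? ll1 : ll2;
    double dl = dprior;
    arma::mat lln(N, T);
    for (int i = 0; i < N; ++i)
      for (int t = 0; t < T; ++t) {
        lln(i, t) = ll_kernel(Oj(i, t), nj(i, t), lpj(i, t) + shift(i, t));
        dl += lln(i, t) - llj(i, t);
      }
    if (std::log(R::runif(0.0, 1.0)) < dl) {
      for (int i = 0; i < N; ++i)
        for (int t = 0; t < T; ++t) lpj(i, t) += shift(i, t);
      llj = lln;
      return true;
    }
    return false;
  };

  const int n_keep = (n_iter - burn_in + thin - 1) / thin;
  const int P = 2 + 2 * K + N + N * K + 2 * N + 2 * N * K + N * T + T
    + 2 * C + 2 + K * K;
  arma::mat draws(n_keep, P);
  arma::vec dev(n_keep);
  int kept = 0, batch = 0;

  for (int iter = 0; iter < n_iter; ++iter) {
    bool adapting = iter < burn_in;

    for (int j = 0; j < 2; ++j) { // intercepts
      AdaptScale& sc = (j == 0) ? sc_al1 : sc_al2;
      double d = R::rnorm(0.0, sc.sd());
      double dp = ldnorm0(alpha(j) + d, sdf)
        - ldnorm0(alpha(j), sdf);
      bool ok = try_shift(j, dp, [&](int, int) { return d; });
      if (ok) alpha(j) += d;
      if (adapting) sc.hit(ok);
    }

    if (t_ag) { // gender-specific fixed spline
      for (int j = 0; j < 2; ++j)
        for (int k = 0; k < K; ++k) {
          AdaptScale& sc = sc_ag[j * K + k];
          double d = R::rnorm(0.0, sc.sd());
          double dp = R::dnorm4(ag(j, k) + d, 0.0, sdf, 1)
            - R::dnorm4(ag(j, k), 0.0, sdf, 1);
          bool ok = try_shift(j, dp,
                              [&](int, int t) { return d * B(t, k); });
          if (ok) ag(j, k) += d;
          if (adapting) sc.hit(ok);
        }
    }

    for (int j = 0; j < 2; ++j) // covariate coefficients
      for (int c = 0; c < C; ++c) {
        AdaptScale& sc = sc_gc[j * C + c];
        double d = R::rnorm(0.0, sc.sd());
        double dp = R::dnorm4(gc(j, c) + d, 0.0, sdf, 1)
          - R::dnorm4(gc(j, c), 0.0, sdf, 1);
        bool ok = try_shift(j, dp,
                            [&](int i, int t) { return d * X[c](i, t); });
        if (ok) gc(j, c) += d;
        if (adapting) sc.hit(ok);
      }

    if (t_b0) { // shared spatial effects (vague normal prior)
      for (int i = 0; i < N; ++i) {
        double d = R::rnorm(0.0, sc_b0.sd());
        double b0p = b0(i) + d;
        double dl = ldnorm0(b0p, sdf)
          - ldnorm0(b0(i), sdf);
        arma::rowvec l1(T), l2(T);
        for (int t = 0; t < T; ++t) {
          l1(t) = ll_kernel(O1(i, t), n1(i, t), lp1(i, t) + d * delta(t));
          l2(t) = ll_kernel(O2(i, t), n2(i, t), lp2(i, t) + d / delta(t));
          dl += l1(t) - ll1(i, t) + l2(t) - ll2(i, t);
        }
        bool ok = std::log(R::runif(0.0, 1.0)) < dl;
        if (ok) {
          b0(i) = b0p;
          for (int t = 0; t < T; ++t) {
            shared(i, t) += d;
            lp1(i, t) += d * delta(t);
            lp2(i, t) += d / delta(t);
          }
          ll1.row(i) = l1; ll2.row(i) = l2;
        }
        if (adapting) sc_b0.hit(ok);
      }
      // recentre the shared spatial level (GeoBUGS convention); the
      // delta_t weighting admits no exact intercept transfer
      double mb = arma::mean(b0);
      if (mb != 0.0) {
        b0 -= mb;
        for (int i = 0; i < N; ++i)
          for (int t = 0; t < T; ++t) {
            shared(i, t) -= mb;
            lp1(i, t) -= mb * delta(t);
            lp2(i, t) -= mb / delta(t);
            ll1(i, t) = ll_kernel(O1(i, t), n1(i, t), lp1(i, t));
            ll2(i, t) = ll_kernel(O2(i, t), n2(i, t), lp2(i, t));
          }
      }
    }

    if (t_bs) { // shared MCAR spline rows
      for (int i = 0; i < N; ++i) {
        arma::rowvec d(K);
        for (int k = 0; k < K; ++k) d(k) = R::rnorm(0.0, sc_bs.sd());
        arma::rowvec bi = bs.row(i), bp = bi + d;
        double dq = 0.0;
        for (int j : g.nb[i]) {
          arma::rowvec d1 = bp - bs.row(j), d0 = bi - bs.row(j);
          dq += arma::as_scalar(d1 * Gam * d1.t() - d0 * Gam * d0.t());
        }
        double dl = -0.5 * dq;
        arma::rowvec l1(T), l2(T), ds(T);
        for (int t = 0; t < T; ++t) {
          ds(t) = arma::dot(d, B.row(t));
          l1(t) = ll_kernel(O1(i, t), n1(i, t), lp1(i, t) + ds(t) * delta(t));
          l2(t) = ll_kernel(O2(i, t), n2(i, t), lp2(i, t) + ds(t) / delta(t));
          dl += l1(t) - ll1(i, t) + l2(t) - ll2(i, t);
        }
        bool ok = std::log(R::runif(0.0, 1.0)) < dl;
        if (ok) {
          bs.row(i) = bp;
          for (int t = 0; t < T; ++t) {
            shared(i, t) += ds(t);
            lp1(i, t) += ds(t) * delta(t);
            lp2(i, t) += ds(t) / delta(t);
          }
          ll1.row(i) = l1; ll2.row(i) = l2;
        }
        if (adapting) sc_bs.hit(ok);
      }
      // recentre columns; the delta_t weighting admits no exact fixed-effect
      // transfer, so the predictor moves with the recentred coefficients
      arma::rowvec m = arma::mean(bs, 0);
      if (arma::norm(m) > 0) {
        bs.each_row() -= m;
        for (int t = 0; t < T; ++t) {
          double shift = arma::dot(m, B.row(t));
          for (int i = 0; i < N; ++i) {
            shared(i, t) -= shift;
            lp1(i, t) -= shift * delta(t);
            lp2(i, t) -= shift / delta(t);
            ll1(i, t) = ll_kernel(O1(i, t), n1(i, t), lp1(i, t));
            ll2(i, t) = ll_kernel(O2(i, t), n2(i, t), lp2(i, t));
          }
        }
      }
    }

    if (t_bg) { // gender-specific spatial effects
      for (int j = 0; j < 2; ++j) {
        const arma::mat& Oj = (j == 0) ? O1 : O2;
        const arma::mat& nj = (j == 0) ? n1 : n2;
        arma::mat& lpj = (j == 0) ? lp1 : lp2;
        arma::mat& llj = (j == 0) ? ll1 : ll2;
        for (int i = 0; i < N; ++i) {
          double d = R::rnorm(0.0, sc_bg.sd());
          double bp = bg(j, i) + d;
          double dl = ldnorm0(bp, sdf)
            - R::dnorm4(bg(j, i), 0.0, sdf, 1);
          arma::rowvec lln(T);
          for (int t = 0; t < T; ++t) {
            lln(t) = ll_kernel(Oj(i, t), nj(i, t), lpj(i, t) + d);
            dl += lln(t) - llj(i, t);
          }
          bool ok = std::log(R::runif(0.0, 1.0)) < dl;
          if (ok) { bg(j, i) = bp; lpj.row(i) += d; llj.row(i) = lln; }
          if (adapting) sc_bg.hit(ok);
        }
        // transfer the level to alpha_j (lp unchanged)
        double mg = arma::mean(bg.row(j));
        bg.row(j) -= mg;
        alpha(j) += mg;
      }
    }

    if (t_rs) { // gender-specific random spline rows (ICAR per column)
      for (int j = 0; j < 2; ++j) {
        const arma::mat& Oj = (j == 0) ? O1 : O2;
        const arma::mat& nj = (j == 0) ? n1 : n2;
        arma::mat& lpj = (j == 0) ? lp1 : lp2;
        arma::mat& llj = (j == 0) ? ll1 : ll2;
        arma::mat& rj = rs.slice(j);
        for (int i = 0; i < N; ++i) {
          arma::rowvec d(K);
          for (int k = 0; k < K; ++k) d(k) = R::rnorm(0.0, sc_rs.sd());
          arma::rowvec ri = rj.row(i), rp = ri + d;
          double dq = 0.0;
          for (int jj : g.nb[i]) {
            arma::rowvec d1 = rp - rj.row(jj), d0 = ri - rj.row(jj);
            dq += arma::dot(d1, d1) - arma::dot(d0, d0);
          }
          double dl = -0.5 * tau_b * dq;
          arma::rowvec lln(T), ds(T);
          for (int t = 0; t < T; ++t) {
            ds(t) = arma::dot(d, B.row(t));
            lln(t) = ll_kernel(Oj(i, t), nj(i, t), lpj(i, t) + ds(t));
            dl += lln(t) - llj(i, t);
          }
          bool ok = std::log(R::runif(0.0, 1.0)) < dl;
          if (ok) {
            rj.row(i) = rp;
            for (int t = 0; t < T; ++t) lpj(i, t) += ds(t);
            llj.row(i) = lln;
          }
          if (adapting) sc_rs.hit(ok);
        }
        // recentre columns; transfer to the gender fixed spline
        arma::rowvec m = arma::mean(rj, 0);
        rj.each_row() -= m;
        if (t_ag) {
          ag.row(j) += m;
        } else {
          for (int t = 0; t < T; ++t) {
            double shift = arma::dot(m, B.row(t));
            for (int i = 0; i < N; ++i) {
              lpj(i, t) -= shift;
              llj(i, t) = ll_kernel(Oj(i, t), nj(i, t), lpj(i, t));
            }
          }
        }
      }
    }

    if (t_bs && t_rs) {
      // swap move along the (bs_ik, rs_1ik, rs_2ik) ~ (1, -1, -1)
      // direction, which single-site updates traverse slowly; the CAR
      // priors keep it bounded and the delta_t weighting identifies it
      for (int i = 0; i < N; ++i) {
        arma::rowvec m(K);
        for (int k = 0; k < K; ++k) m(k) = R::rnorm(0.0, sc_sw.sd());
        arma::rowvec bi = bs.row(i), bp = bi + m;
        arma::rowvec r0 = rs.slice(0).row(i), r0p = r0 - m;
        arma::rowvec r1 = rs.slice(1).row(i), r1p = r1 - m;
        double dq = 0.0, dqr = 0.0;
        for (int j : g.nb[i]) {
          arma::rowvec d1 = bp - bs.row(j), d0 = bi - bs.row(j);
          dq += arma::as_scalar(d1 * Gam * d1.t() - d0 * Gam * d0.t());
          arma::rowvec e1 = r0p - rs.slice(0).row(j);
          arma::rowvec e0 = r0 - rs.slice(0).row(j);
          dqr += arma::dot(e1, e1) - arma::dot(e0, e0);
          arma::rowvec f1 = r1p - rs.slice(1).row(j);
          arma::rowvec f0 = r1 - rs.slice(1).row(j);
          dqr += arma::dot(f1, f1) - arma::dot(f0, f0);
        }
        double dl = -0.5 * dq - 0.5 * tau_b * dqr;
        arma::rowvec l1(T), l2(T), ds(T);
        for (int t = 0; t < T; ++t) {
          ds(t) = arma::dot(m, B.row(t));
          l1(t) = ll_kernel(O1(i, t), n1(i, t),
                            lp1(i, t) + ds(t) * (delta(t) - 1.0));
          l2(t) = ll_kernel(O2(i, t), n2(i, t),
                            lp2(i, t) + ds(t) * (1.0 / delta(t) - 1.0));
          dl += l1(t) - ll1(i, t) + l2(t) - ll2(i, t);
        }
        bool ok = std::log(R::runif(0.0, 1.0)) < dl;
        if (ok) {
          bs.row(i) = bp;
          rs.slice(0).row(i) = r0p;
          rs.slice(1).row(i) = r1p;
          for (int t = 0; t < T; ++t) {
            shared(i, t) += ds(t);
            lp1(i, t) += ds(t) * (delta(t) - 1.0);
            lp2(i, t) += ds(t) * (1.0 / delta(t) - 1.0);
          }
          ll1.row(i) = l1; ll2.row(i) = l2;
        }
        if (adapting) sc_sw.hit(ok);
      }
      // the swap moves rows without preserving column sums; recentre the
      // shared spline (predictor follows) and the gender splines
      // (transferred into the fixed splines, predictor unchanged)
      arma::rowvec mbs = arma::mean(bs, 0);
      if (arma::norm(mbs) > 0) {
        bs.each_row() -= mbs;
        for (int t = 0; t < T; ++t) {
          double shift = arma::dot(mbs, B.row(t));
          for (int i = 0; i < N; ++i) {
            shared(i, t) -= shift;
            lp1(i, t) -= shift * delta(t);
            lp2(i, t) -= shift / delta(t);
            ll1(i, t) = ll_kernel(O1(i, t), n1(i, t), lp1(i, t));
            ll2(i, t) = ll_kernel(O2(i, t), n2(i, t), lp2(i, t));
          }
        }
      }
      for (int j = 0; j < 2; ++j) {
        arma::mat& rj = rs.slice(j);
        arma::rowvec m = arma::mean(rj, 0);
        rj.each_row() -= m;
        if (t_ag) {
          ag.row(j) += m;
        } else {
          const arma::mat& Oj = (j == 0) ? O1 : O2;
          const arma::mat& nj = (j == 0) ? n1 : n2;
          arma::mat& lpj = (j == 0) ? lp1 : lp2;
          arma::mat& llj = (j == 0) ? ll1 : ll2;
          for (int t = 0; t < T; ++t) {
            double shift = arma::dot(m, B.row(t));
            for (int i = 0; i < N; ++i) {
              lpj(i, t) -= shift;
              llj(i, t) = ll_kernel(Oj(i, t), nj(i, t), lpj(i, t));
            }
          }
        }
      }
    }

    if (t_int) { // spatio-temporal interaction, ICAR in space per wave
      for (int t = 0; t < T; ++t) {
        for (int i = 0; i < N; ++i) {
          double d = R::rnorm(0.0, sc_bt.sd());
          double btp = bt(i, t) + d;
          double dq = 0.0;
          for (int j : g.nb[i]) {
            double d1 = btp - bt(j, t), d0 = bt(i, t) - bt(j, t);
            dq += d1 * d1 - d0 * d0;
          }
          double dl = -0.5 * tau_beta * dq;
          double l1 = ll_kernel(O1(i, t), n1(i, t), lp1(i, t) + d);
          double l2 = ll_kernel(O2(i, t), n2(i, t), lp2(i, t) + d);
          dl += l1 - ll1(i, t) + l2 - ll2(i, t);
          bool ok = std::log(R::runif(0.0, 1.0)) < dl;
          if (ok) {
            bt(i, t) = btp;
            lp1(i, t) += d; lp2(i, t) += d;
            ll1(i, t) = l1; ll2(i, t) = l2;
          }
          if (adapting) sc_bt.hit(ok);
        }
        // recentre the wave's column (no exact fixed-effect counterpart)
        double m = arma::mean(bt.col(t));
        if (m != 0.0) {
          bt.col(t) -= m;
          for (int i = 0; i < N; ++i) {
            lp1(i, t) -= m; lp2(i, t) -= m;
            ll1(i, t) = ll_kernel(O1(i, t), n1(i, t), lp1(i, t));
            ll2(i, t) = ll_kernel(O2(i, t), n2(i, t), lp2(i, t));
          }
        }
      }
    }

    if (t_dw) { // log shared weights
      for (int t = 0; t < T; ++t) {
        double d = R::rnorm(0.0, sc_ld.sd());
        double ldp = ld(t) + d, dp = std::exp(ldp);
        double dl = ldnorm0(ldp, ld_sd)
          - ldnorm0(ld(t), ld_sd);
        arma::vec l1(N), l2(N);
        for (int i = 0; i < N; ++i) {
          double e1 = lp1(i, t) + shared(i, t) * (dp - delta(t));
          double e2 = lp2(i, t) + shared(i, t) * (1.0 / dp - 1.0 / delta(t));
          l1(i) = ll_kernel(O1(i, t), n1(i, t), e1);
          l2(i) = ll_kernel(O2(i, t), n2(i, t), e2);
          dl += l1(i) - ll1(i, t) + l2(i) - ll2(i, t);
        }
        bool ok = std::log(R::runif(0.0, 1.0)) < dl;
        if (ok) {
          for (int i = 0; i < N; ++i) {
            lp1(i, t) += shared(i, t) * (dp - delta(t));
            lp2(i, t) += shared(i, t) * (1.0 / dp - 1.0 / delta(t));
            ll1(i, t) = l1(i); ll2(i, t) = l2(i);
          }
          ld(t) = ldp; delta(t) = dp;
        }
        if (adapting) sc_ld.hit(ok);
      }
    }

    // precisions
    if (t_int) {
      double q = 0.0;
      for (int t = 0; t < T; ++t) q += icar_quad(bt.col(t), g);
      tau_beta = update_tau(tau_beta, T * (N - 1) / 2.0, 0.5 * q,
                            variant, shp, rte, sc_tb, adapting);
    }
    if (t_rs) {
      double q = 0.0;
      for (int j = 0; j < 2; ++j)
        for (int k = 0; k < K; ++k)
          q += icar_quad(rs.slice(j).col(k), g);
      tau_b = update_tau(tau_b, 2 * K * (N - 1) / 2.0, 0.5 * q,
                         variant, shp, rte, sc_tbb, adapting);
    }
    if (t_bs) {
      arma::mat Sb = mcar_crossprod(bs, g);
      Gam = rwishart_rate(wdf + double(N - 1), wR + Sb);
    }

    if (adapting && (iter + 1) % 50 == 0) {
      batch++;
      sc_al1.adapt(batch); sc_al2.adapt(batch); sc_b0.adapt(batch);
      sc_bg.adapt(batch); sc_bs.adapt(batch); sc_rs.adapt(batch);
      sc_bt.adapt(batch); sc_ld.adapt(batch); sc_sw.adapt(batch);
      sc_tb.adapt(batch); sc_tbb.adapt(batch);
      for (auto& sck : sc_ag) sck.adapt(batch);
      for (auto& scc : sc_gc) scc.adapt(batch);
    }

    if (iter >= burn_in && (iter - burn_in) % thin == 0) {
      int p = 0;
      draws(kept, p++) = alpha(0);
      draws(kept, p++) = alpha(1);
      for (int j = 0; j < 2; ++j)
        for (int k = 0; k < K; ++k) draws(kept, p++) = ag(j, k);
      for (int i = 0; i < N; ++i) draws(kept, p++) = b0(i);
      for (int k = 0; k < K; ++k)
        for (int i = 0; i < N; ++i) draws(kept, p++) = bs(i, k);
      for (int j = 0; j < 2; ++j)
        for (int i = 0; i < N; ++i) draws(kept, p++) = bg(j, i);
      for (int j = 0; j < 2; ++j)
        for (int k = 0; k < K; ++k)
          for (int i = 0; i < N; ++i) draws(kept, p++) = rs(i, k, j);
      for (int t = 0; t < T; ++t)
        for (int i = 0; i < N; ++i) draws(kept, p++) = bt(i, t);
      for (int t = 0; t < T; ++t) draws(kept, p++) = ld(t);
      for (int j = 0; j < 2; ++j)
        for (int c = 0; c < C; ++c) draws(kept, p++) = gc(j, c);
      draws(kept, p++) = tau_beta;
      draws(kept, p++) = tau_b;
      for (int l = 0; l < K; ++l)
        for (int k = 0; k < K; ++k) draws(kept, p++) = Gam(k, l);
      dev(kept) = deviance_slab(O1, n1, lp1) + deviance_slab(O2, n2, lp2);
      kept++;
    }
  }

  return List::create(_["draws"] = draws, _["deviance"] = dev);
}
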