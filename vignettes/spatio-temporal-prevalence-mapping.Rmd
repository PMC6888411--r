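---
title: "Spatio-temporal disease mapping of survey prevalence with shared components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatio-temporal disease mapping of survey prevalence with shared components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stprev)
```

## The problem

Hypertension-style outcomes in multi-wave health surveys arrive as areal
binomial panels: for region $i$, survey wave $t$ (and possibly sex $j$),
one observes cases $O_{it}$ out of $n_{it}$ participants. The outcome is
common (prevalence 10–40%), so the rare-disease Poisson/log-link
machinery of classical disease mapping is replaced by a binomial
likelihood with a logit link, and with only a handful of regions the
region-level estimates benefit from borrowing strength across both space
and time. `stprev` implements two Bayesian models for such panels:

* a **spatio-temporal BYM model** for a single outcome series, and
* a **spatio-temporal shared component model (SCM)** for two outcome
  series (here the two sexes) sharing a common spatial and
  spatio-temporal component.

Both use cubic regression B-splines for time, intrinsic CAR priors for
space, and are fitted by MCMC with DIC-based model comparison. A
synthetic-data generator emulates the structure of the motivating
restricted-access survey (7 contiguous Chinese provinces observed at 9
waves from 1991 to 2015, cell totals in the hundreds to low thousands,
prevalence rising from roughly 0.12 to 0.35), so that every stage is
testable without the survey microdata.

## Models

### Spatio-temporal BYM

For one outcome,

$$O_{it} \sim \mathrm{Bin}(n_{it},\ p_{it}), \qquad
  \operatorname{logit}(p_{it}) = \alpha_0 + S_0(t) + u_{i0} + s_{i0} + RS_i(t),$$

with a global spline trend $S_0(t) = \sum_{k=1}^K a_k B_k(t)$ and a
region-specific trend $RS_i(t) = \sum_k b_{ik} B_k(t)$. The region level
is the classic convolution $b_{i0} = u_{i0} + s_{i0}$: an unstructured
iid normal effect (precision $\tau_u$) plus a spatially structured ICAR
effect (precision $\tau_s$). The matrix of random spline coefficients
$b = (b_{ik})$ carries an intrinsic multivariate CAR prior with precision
$(D - W) \otimes \Gamma$, where $W$ is the binary adjacency matrix, $D$
the diagonal neighbour-count matrix and $\Gamma$ a $K \times K$ SPD
precision coupling the basis columns.

### Shared component model

For two outcomes ($j = 1$ males, $j = 2$ females),

$$\operatorname{logit}(p_{1it}) = \alpha_1 + (b_{0i} + RS_{0i}(t))\,\delta_t
  + S_1(t) + b_{1i} + RS_{1i}(t) + \beta_{it},$$
$$\operatorname{logit}(p_{2it}) = \alpha_2 + (b_{0i} + RS_{0i}(t))/\delta_t
  + S_2(t) + b_{2i} + RS_{2i}(t) + \beta_{it}.$$

The common spatial level $b_{0i}$ and common region-specific trend
$RS_{0i}(t)$ are split between the sexes by the time-varying weights
$\delta_t$ and $1/\delta_t$; because $\log\delta_t + \log(1/\delta_t) = 0$
the log-weights sum to zero by construction, which is what identifies the
weight. Sex-specific trends $S_j$, spatial levels $b_{ji}$, random spline
coefficients $RS_{ji}$ and a spatio-temporal interaction $\beta_{it}$
(ICAR in space, independent across waves, entering both sexes) complete
the predictor. The headline SCM outputs are the posterior of $\delta_t$
and the variance share
$\eta_j(t) = \operatorname{var}_i(\text{weighted shared}) /
\operatorname{var}_i(\eta_{jit})$, the proportion of the across-region
variance of each sex's predictor explained by the shared component.
Shares can exceed 1 when the shared and sex-specific surfaces are
anticorrelated across regions; `delta_eta_report()` flags rather than
clips such draws.

### Priors

All fixed effects are $N(0, 10000)$ — the second argument is a
**variance** throughout this package. Scalar precisions are
$\mathrm{gamma}(5, 5\times 10^{-4})$ (shape–rate), the MCAR precision is
Wishart with identity scale and $df = K$, and $\log\delta_t \sim
N(0, 0.169)$. The 0.169 variance is a calibration, not an arbitrary
number: it puts $\delta_t^2$ inside $[1/5, 5]$ with probability 0.95,

```{r}
delta_sq_band_probability(log_delta_var = 0.169, upper = 5)
```

and this closed-form check (confirmed by Monte Carlo in the test-suite)
is also what settles the variance-versus-precision reading of the
$N(\cdot,\cdot)$ notation: the BUGS precision reading would give a
probability of essentially 1.

Two notational wrinkles deserve a note. First, the MCAR precision is
stated over an "$L - W$" product; since $W$ is $N \times N$, the only
dimensionally consistent reading is $L = D$, the neighbour-count
diagonal, giving the standard intrinsic MCAR $(D - W) \otimes \Gamma$ —
that is what is implemented and what `log_mcar()`'s dense-Kronecker
oracle tests pin down. Second, the shared spatial level $b_{0i}$ and the
sex-specific levels $b_{ji}$ carry plain vague normals rather than CAR
priors, which follows the stated prior choices for the motivating
analysis; the spatially structured part of the SCM lives in
$RS_{0i}(t)$, $\beta_{it}$ and the sex-specific splines.

## Temporal basis

Waves are centred at a reference year (default 2004) to handle the
unequal survey spacing. With $L$ interior knots, the clamped cubic
B-spline basis has $L + 4$ functions whose values sum to one at every
time point; the first column is dropped, leaving $K = L + 3$ columns, so
the model intercept stays identifiable. Dropping the *first* column has
a useful consequence: every remaining basis function vanishes at the
first wave, so $\alpha_0$ (and $\alpha_j$) is exactly the first-wave
logit level and the spline measures change relative to it. Interior
knots default to one knot at the centred reference year; further knots
are added by `forward_knot_selection()`, which greedily adds the
candidate (by default the centred interior waves) that most reduces DIC
and stops when the best reduction drops below 2 — the conventional
materiality threshold for DIC differences. At desk-scale MCMC settings
the DIC estimate itself carries Monte-Carlo noise of a few units, so
occasional extra knots are expected; the trace returned alongside the
selection makes that visible.

## Inference

The paper-scale protocol (2 chains of 100,000 iterations, 50,000
burn-in, thin 10; `mcmc_config_full()`) is the documented default for
real analyses. The test-suite and examples run a desk-scale protocol
(`mcmc_config()`: 2 chains × 4,000 iterations, 2,000 burn-in, thin 2)
chosen so a BYM fit takes ~0.2 s and an SCM fit ~0.5 s; kept draws are
always `chains × ceiling((n_iter − burn_in)/thin)`.

The sampler is an adaptive Metropolis-within-Gibbs scheme written in
C++:

* conjugate Gibbs updates for the gamma-prior precisions and the
  Wishart-prior MCAR precision;
* random-walk Metropolis for everything else, with per-block proposal
  scales adapted during burn-in only (frozen afterwards, so kept draws
  come from a fixed transition kernel);
* sum-to-zero recentring of every intrinsic CAR block after each sweep
  (the GeoBUGS `car.normal` convention). Where an exactly confounded
  fixed effect exists the subtracted mean is transferred to it (BYM
  spatial level → intercept, spline-coefficient column means → fixed
  spline coefficients), leaving the linear predictor untouched; the SCM
  shared-spline columns and the per-wave interaction means have no exact
  fixed-effect counterpart because of the $\delta_t$ weighting and are
  recentred without compensation;
* two extra move types that leave the target unchanged but traverse
  known slow directions: an interweaved rescaling move for each BYM
  precision (the funnel between a precision and its block's scale under
  the informative gamma prior), and swap moves along the confounded
  $u_i/s_i$ and shared-versus-sex-specific spline directions.

All randomness flows through R's RNG, so a fit is bit-reproducible from
`mcmc_config(seed = )`; chains use seed offsets. Default initial values
are crude empirical logits (pooled intercept, least-squares trend on the
basis, halved region residuals) plus per-chain jitter. A genuine prior
draw from the $N(0, 10000)$ fixed-effect priors would start chains at
$|\operatorname{logit}| \approx 100$, i.e. numerically degenerate
prevalences, which is why data-informed initials — standard practice in
the BUGS lineage — are the default; `init = "prior_draw"` and `"zeros"`
remain available for robustness checks.

### What is identified, and the convergence gate

Three directions of the parameter space are only weakly identified, a
property of the models rather than the sampler:

* the split of the BYM region level into $u_i$ versus $s_i$ (only the
  convolution $u_i + s_i$ enters the likelihood);
* the split of the SCM spatial level into shared $b_{0i}$ versus the two
  sex-specific $b_{ji}$ (identified only through $\delta_t \neq 1$);
* likewise the shared versus sex-specific spline coefficients.

Reporting functions gate on split-chain Brooks–Gelman–Rubin
$\hat R < 1.1$ over the **monitored** blocks: all identified quantities
(intercepts, trends, interaction, weights, precisions, and for the BYM
the derived convolution `conv[i]`). The unidentified splits are reported
but not gated — at the full 100,000-iteration protocol they mix, at desk
scale they wander, and their posteriors are legitimately diffuse. The
practical consequence is that SCM variance shares $\eta_j(t)$ carry wide
intervals on weakly-shared synthetic data.

### DIC

`compute_dic()` reports $\bar D$ (posterior mean deviance), the plug-in
deviance $D(\bar\theta)$ at the posterior mean of the linear-predictor
parameters, $p_D = \bar D - D(\bar\theta)$ and
$\mathrm{DIC} = \bar D + p_D$. The plug-in is evaluated through the
pure-R linear predictors, which doubles as a cross-check of the C++
likelihood bookkeeping; a dedicated test additionally recomputes the C++
deviance trace in R at individual kept draws and finds exact agreement.

### Prior sensitivity

`sensitivity_harness()` refits a model under the three precision-prior
variants used in the motivating sensitivity analysis —
$\tau \sim \mathrm{gamma}(5, 5\times10^{-4})$, $\sigma \sim U(0,1)$, and
$\sigma^2 \sim N(0, 100)I(0,)$ — applying the variant to every
gamma-prior precision of the refitted model, and tabulates posterior
means and 95% intervals of the exponentiated headline effects together
with DIC and $p_D$ per variant. Variants 2 and 3 lose conjugacy and use
Metropolis updates on $\log\tau$ with the appropriate Jacobians; the
implied densities are verified by numerical integration in the
test-suite.

## Moran's I screening

Before any spatial model is fitted, `moran_screening()` tests each
wave-and-sex slice of crude prevalences for global spatial
autocorrelation using Moran's I with binary adjacency weights and a
one-sided Monte-Carlo permutation test (default 9,999 permutations),
$p = (1 + \#\{I^* \ge I_{\mathrm{obs}}\})/(1 + n_{\mathrm{perm}})$. At
$N = 7$ regions a permutation test is the only defensible choice: it is
exact under exchangeability, whereas the normal approximation is poor,
and with so few regions the discreteness of the permutation distribution
matters — a two-valued cluster indicator ties with rival partitions and
cannot reach $p \le 0.05$ even when perfectly aligned with contiguity,
while a graded gradient can. The permutation p-values are verified to be
calibrated under an exchangeable null in the test-suite.

## The synthetic generator

`chns_like_preset()` documents a fixed synthetic truth whose pooled
prevalence rises from about 0.12 at the 1991 wave to about 0.35 at 2015
with males above females — the printed trajectory of the motivating
survey (11.7% → 34.5% pooled; 12.8% → 38.1% male, 10.8% → 31.5% female).
The sex-specific logit trends interpolate those anchors linearly on the
logit scale and are projected onto the generating basis; all latent
values are invented and labelled synthetic. Random-effect scales are
fixed once at what province-level disease-mapping studies typically
show: spatial and unstructured levels with standard deviation 0.15–0.2
on the log-odds scale (relative risks spanning roughly ±30% across
provinces), random spline and interaction effects at 0.1. ICAR and MCAR
blocks are drawn exactly from their intrinsic priors via the spectral
decomposition of $D - W$; free levels are centred so the intercepts are
the identified baselines, matching the sampler's constraint handling.
Cell totals are drawn uniformly from 200–1,500 per sex-region-wave
(per-cell totals are not published; this spans the plausible range for
the survey's provincial samples). Optional regional covariates
(proportions aged 60+, overweight, ever-smokers, drinkers) drift
linearly over the study period with regional jitter of 0.03 and are
clipped to $[0.01, 0.99]$.

What the generator does **not** emulate: survey design weights,
within-region clustering of households, measurement error in blood
pressure, repeated measurements on the same individuals across waves,
and informative dropout. Passing recovery tests on this generator
therefore demonstrates correctness of the estimation machinery under the
stated model, not robustness to those real-data features.

Covariates deserve a caveat: with regional jitter 0.03 the preset's
covariates have almost no cross-region contrast, so regional-level odds
ratios are barely identified from 7 regions — exactly the situation of
real regional-proportion covariates. The covariate recovery experiment
in the test-suite therefore uses a contrast-rich configuration (regional
sd 0.15) to test the machinery rather than the data's information
content. In time-varying mode each covariate's effect is
$\gamma_{c0} + \sum_k \gamma_{ck} B_k(t)$ — the base coefficient is kept
so the constant effect is nested (the intercept-dropped basis vanishes
at the first wave and could not represent it alone).

## Numerical choices and degenerate inputs

* Binomial likelihood ratios use the kernel
  $O\eta - n\log(1 + e^\eta)$ (stable via a large-$\eta$ branch); full
  deviances including binomial coefficients are computed per kept draw.
* Intrinsic CAR densities are evaluated on the sum-to-zero subspace with
  normalizers $(N-1)/2\,\log\tau$ and $(N-1)/2\,\log|\Gamma|$; inputs off
  the subspace are rejected, as are isolated regions and disconnected
  graphs when a CAR prior is requested.
* Wishart draws use the Bartlett decomposition with R's RNG, keeping the
  whole fit reproducible from one integer seed.
* Proposal-scale adaptation uses batch acceptance rates with a
  Robbins–Monro-style step, targets 0.44 for scalar and 0.23 for block
  proposals, and hard log-scale bounds; adaptation stops at the end of
  burn-in.
* Zero-variance parameters (disabled blocks) report $\hat R = 1$ and
  autocorrelation 0 beyond lag 0 instead of `NaN`.
* CSV round-trips write 15 significant digits; fit serialisation
  (`save_fit()`) stores one draw matrix per chain plus a versioned JSON
  summary.

## Problem sizes used in tests

The test-suite runs everything at the study's dimensions (7 regions, 9
waves, 2 sexes) with desk-scale MCMC (2 × 4,000 iterations; fixture
fits use 2 × 1,500): 20-replicate recovery experiments for each model,
10-seed DIC model-comparison experiments, 100-seed generator property
checks, a 200-seed permutation-calibration experiment, and a
$10^6$-draw Monte-Carlo confirmation of the prior calibration. These
sizes were chosen so the entire suite completes in well under a minute
while keeping the binomial and Monte-Carlo standard errors small enough
for the stated acceptance margins.

## Known limitations

* Desk-scale runs do not resolve the unidentified splits discussed
  above; treat reported `u`/`s`, `b0`/`bg` and shared/sex-specific
  spline splits (and hence $\eta_j(t)$) as requiring full-protocol runs.
* The interaction $\beta_{it}$ is ICAR in space and independent across
  waves; temporally structured interactions are out of scope.
* Only intrinsic (not proper) CAR priors are provided, and only binomial
  likelihoods with a logit link.
* The permutation test addresses global clustering only; local
  (region-level) Moran statistics are not implemented.
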